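#' Simulate a landmark cohort with latent structure and a planted contrast
#'
#' Generates `n` landmark configurations around a template as
#' `template + latent shape variation + covariate effects + group shift +
#' isotropic noise`. Latent bases are Gaussian random fields smoothed over
#' the template lattice so that nearby landmarks covary, which is the
#' correlation structure the RV-based segmentation expects in real faces.
#' Covariate effects are linear with fixed (seed-determined) coefficient
#' fields so the residualization stage has a known truth. A binary group
#' label shifts the mean by `effect_size * effect_direction`, emulating a
#' parents-versus-unselected contrast.
#'
#' @param template An [make_template()] object.
#' @param n Number of individuals.
#' @param frac_group1 Fraction of individuals in group 1 (the "parent"-like
#'   group).
#' @param latent_rank Number of smooth latent shape axes.
#' @param latent_sds Standard deviations of the latent scores; recycled to
#'   `latent_rank`.
#' @param effect_direction Unit 3p-vector of the planted group effect, e.g.
#'   from [localized_direction()]; `NULL` for no group effect.
#' @param effect_size Scalar multiplier of the group shift (template units).
#' @param covariate_sd Scale of the covariate coefficient fields; set 0 to
#'   silence covariate effects.
#' @param noise_sd Isotropic per-coordinate noise standard deviation.
#' @param smooth_bandwidth Gaussian smoothing bandwidth of the latent fields.
#' @param seed Integer seed; the whole draw is a pure function of the
#'   arguments.
#'
#' @return A list of class `endo_cohort`: `configs` (n x p x 3 array),
#'   `covariates` (tibble: id, sex, age, height, weight), `group`
#'   (integer 0/1), `truth` (list with the latent bases, covariate
#'   coefficient fields and planted direction), `template`.
#' @export
simulate_cohort <- function(template, n,
                            frac_group1 = 0.5,
                            latent_rank = 12,
                            latent_sds = 0.12 * 0.9^(0:11),
                            effect_direction = NULL,
                            effect_size = 0,
                            covariate_sd = 0.02,
                            noise_sd = 0.02,
                            smooth_bandwidth = 0.3,
                            seed = 1) {
  stopifnot(inherits(template, "endo_template"))
  n <- check_count(n, 4L, "n")
  latent_rank <- check_count(latent_rank, 0L, "latent_rank")
  latent_sds <- rep_len(latent_sds, latent_rank)
  if (any(latent_sds <= 0) || noise_sd <= 0) abort("sds must be positive")
  if (!is.null(effect_direction)) {
    if (length(effect_direction) != 3L * template$p)
      abort("`effect_direction` must have length 3p")
    if (abs(sqrt(sum(effect_direction^2)) - 1) > 1e-6)
      abort("`effect_direction` must have unit norm")
  }
  set.seed(seed)
  p <- template$p

  # smoothing kernel over the lattice: nearby landmarks get correlated loads
  D2 <- as.matrix(stats::dist(template$coords))^2
  K <- exp(-D2 / (2 * smooth_bandwidth^2))

  smooth_field <- function() {
    f <- K %*% matrix(stats::rnorm(p * 3), p, 3)
    f / sqrt(sum(f^2))
  }
  bases <- if (latent_rank > 0)
    lapply(seq_len(latent_rank), function(k) smooth_field()) else list()

  cov_fields <- lapply(1:4, function(j) smooth_field() * covariate_sd)

  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::runif(n, 18, 70)
  height <- stats::rnorm(n, 170 + 12 * sex, 7)
  weight <- stats::rnorm(n, 70 + 8 * sex, 10)
  group <- as.integer(seq_len(n) <= round(n * frac_group1))
  group <- sample(group)                    # random interleaving

  z_age <- (age - 44) / 15; z_h <- (height - 176) / 10; z_w <- (weight - 74) / 11
  covs <- cbind(sex - 0.5, z_age, z_h, z_w)

  configs <- array(0, dim = c(n, p, 3))
  scores <- if (latent_rank > 0)
    matrix(stats::rnorm(n * latent_rank), n, latent_rank) %*% diag(latent_sds, latent_rank)
  else matrix(0, n, 0)
  eff <- if (is.null(effect_direction)) matrix(0, p, 3) else
    unflatten_config(effect_direction) * effect_size

  for (i in seq_len(n)) {
    ci <- template$coords
    for (k in seq_len(latent_rank)) ci <- ci + scores[i, k] * bases[[k]]
    for (j in 1:4) ci <- ci + covs[i, j] * cov_fields[[j]]
    ci <- ci + group[i] * eff
    configs[i, , ] <- ci + matrix(stats::rnorm(p * 3, 0, noise_sd), p, 3)
  }

  structure(list(
    configs = configs,
    covariates = tibble(id = sprintf("ind%04d", seq_len(n)),
                        sex = sex, age = age, height = height, weight = weight),
    group = group,
    truth = list(bases = bases, cov_fields = cov_fields,
                 effect_direction = effect_direction, effect_size = effect_size,
                 latent_scores = scores),
    template = template
  ), class = "endo_cohort")
}

#' @export
print.endo_cohort <- function(x, ...) {
  cat(sprintf("<endo_cohort> %d individuals x %d landmarks (group 1: %d)\n",
              dim(x$configs)[1], dim(x$configs)[2], sum(x$group)))
  invisible(x)
}
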