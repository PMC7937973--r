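#' One-component PLSR contrast between two groups in a segment's PC space
#'
#' Regresses the segment PC scores (responses) on the centered binary group
#' label with a single-component PLSR. With one binary predictor the PLS
#' direction is algebraically parallel to the difference of the group mean
#' vectors; it is returned as a unit vector oriented so that moving along
#' it increases the predicted mean of group 1 (the "parents"-like group).
#' The pooled effect size is `r2 = 1 - SS_res / SS_tot` over the k
#' responses.
#'
#' @param pc_scores n x k matrix of per-individual segment PC scores.
#' @param group Binary 0/1 vector; group 1 is the contrast's target group.
#' @return A list: `direction` (unit k-vector), `r2`.
#' @export
plsr_contrast <- function(pc_scores, group) {
  pc_scores <- as.matrix(pc_scores)
  group <- as.numeric(group)
  if (length(unique(group)) != 2L || !all(group %in% c(0, 1)))
    abort("`group` must be a 0/1 vector with both groups present")
  g <- group - mean(group)
  Yc <- scale(pc_scores, scale = FALSE)
  w <- crossprod(Yc, g)                      # n * cov(Y, g): the PLS weight
  if (sqrt(sum(w^2)) < .Machine$double.eps * nrow(Yc))
    abort("zero between-group covariance: direction undefined")
  # w is a positive multiple of (group-1 mean - group-0 mean), so the unit
  # direction is already oriented toward the group-1 mean
  direction <- as.vector(w) / sqrt(sum(w^2))
  list(direction = direction, r2 = contrast_r2(Yc, g))
}

# pooled R^2 of the one-component PLS fit: fitted Y = projection of each
# response column on the centered group indicator
contrast_r2 <- function(Yc, g) {
  ss_tot <- sum(Yc^2)
  if (ss_tot < .Machine$double.eps) return(0)
  sum(crossprod(Yc, g)^2) / sum(g^2) / ss_tot
}

#' Permutation test of a group contrast's effect size
#'
#' Permutes the group labels and recomputes the one-component PLSR effect
#' size (`r2`) each time; the p-value uses the add-one convention
#' `p = (1 + #(r2_perm >= r2_obs)) / (1 + n_perm)`, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @inheritParams plsr_contrast
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return A list: `r2_obs`, `p_perm`, `n_perm`.
#' @export
permutation_test <- function(pc_scores, group, n_perm = 10000, seed = 1) {
  n_perm <- check_count(n_perm, 99L, "n_perm")
  group <- as.numeric(group)
  if (length(unique(group)) < 2L) abort("`group` is constant")
  Yc <- scale(as.matrix(pc_scores), scale = FALSE)
  g <- group - mean(group)
  r2_obs <- contrast_r2(Yc, g)
  set.seed(seed)
  r2_perm <- vapply(seq_len(n_perm),
                    function(i) contrast_r2(Yc, sample(g)), 1)
  list(r2_obs = r2_obs,
       p_perm = (1 + sum(r2_perm >= r2_obs)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Fit endophenotype traits across all segments
#'
#' For every segment model, projects both cohorts, fits the group contrast
#' and its permutation test, and returns one trait per segment: a unit
#' direction of effect in that segment's PC space, its effect size and
#' permutation p-value.
#'
#' @param shapes n x 3p matrix of aligned, covariate-adjusted
#'   configurations (both groups stacked).
#' @param group Binary 0/1 vector (1 = parents-like group).
#' @param models List of [fit_segment_model()] objects.
#' @param n_perm,seed Passed to [permutation_test()].
#' @return An `endo_traits` object: tibble with `segment_id`, `k`, `r2`,
#'   `p_perm` and list-column `direction`; the models are kept as an
#'   attribute for scoring.
#' @export
fit_traits <- function(shapes, group, models, n_perm = 10000, seed = 1) {
  rows <- purrr::map2(models, seq_along(models), function(m, i) {
    sc <- project_segment(m, shapes)
    ct <- plsr_contrast(sc, group)
    pt <- permutation_test(sc, group, n_perm = n_perm, seed = seed + i)
    tibble(segment_id = m$segment_id, k = m$k, r2 = ct$r2,
           p_perm = pt$p_perm, direction = list(ct$direction))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "models") <- models
  class(out) <- c("endo_traits", class(out))
  out
}

#' Select nominally significant traits
#'
#' Keeps traits whose permutation p-value falls below `alpha`, preserving
#' segment order, and reports how many also pass a Bonferroni threshold
#' for the effective number of independent tests when one is supplied.
#'
#' @param traits An [fit_traits()] tibble (or any tibble with `p_perm`).
#' @param alpha Nominal significance level (default 0.05).
#' @param bonferroni Optional stricter threshold (e.g. `alpha / m_eff`).
#' @return The selected subset, with attribute `n_bonferroni` when
#'   `bonferroni` was given.
#' @export
select_traits <- function(traits, alpha = 0.05, bonferroni = NULL) {
  sel <- dplyr::filter(traits, .data$p_perm < alpha)
  if (!is.null(bonferroni))
    attr(sel, "n_bonferroni") <- sum(traits$p_perm < bonferroni)
  sel
}

#' Cosine distance between a trait direction and an individual's shape
#'
#' `1 - cos(angle)` between the trait's unit direction and the individual's
#' PC vector in the same segment space: 0 when the shape points exactly
#' along the trait (the endophenotype fully present), 1 when orthogonal,
#' 2 when opposite. Scale-invariant in the PC vector.
#'
#' @param direction Unit k-vector (a trait's direction of effect).
#' @param pc Either a k-vector or an n x k matrix of PC scores.
#' @return Numeric vector of cosine distances in `[0, 2]`.
#' @export
cosine_score <- function(direction, pc) {
  if (is.null(dim(pc))) pc <- matrix(pc, nrow = 1)
  nrm <- sqrt(rowSums(pc^2))
  if (any(nrm < .Machine$double.eps)) abort("zero PC vector")
  as.vector(1 - (pc %*% direction) / (nrm * sqrt(sum(direction^2))))
}

#' Score individuals on every (selected) trait
#'
#' Projects each configuration into each trait's segment space and returns
#' the per-individual cosine-distance scores.
#'
#' @param traits An [fit_traits()] object (optionally subset by
#'   [select_traits()]); must carry its segment models.
#' @param shapes n x 3p matrix of configurations to score.
#' @param models Segment models; defaults to the ones stored on `traits`.
#' @return n x n_traits matrix of scores, columns named `seg<segment_id>`.
#' @export
score_traits <- function(traits, shapes, models = attr(traits, "models")) {
  if (is.null(models)) abort("segment models are required for scoring")
  by_id <- stats::setNames(models, vapply(models, function(m) m$segment_id, 1))
  out <- vapply(seq_len(nrow(traits)), function(i) {
    m <- by_id[[as.character(traits$segment_id[i])]]
    cosine_score(traits$direction[[i]], project_segment(m, shapes))
  }, numeric(nrow(shapes)))
  colnames(out) <- sprintf("seg%d", traits$segment_id)
  out
}

#' Effective number of independent tests (Li-Ji)
#'
#' Computes the Pearson correlation matrix of per-individual trait scores,
#' takes its eigenvalues and applies the Li-Ji construction
#' `m_eff = sum( 1(lambda >= 1) + (lambda - floor(lambda)) )` (rounded), a
#' standard eigenvalue-based estimate of how many independent tests a set
#' of correlated traits amounts to. Also returns the Bonferroni threshold
#' `alpha / m_eff`.
#'
#' @param scores n x t matrix of per-individual trait scores (t >= 2).
#' @param alpha Family-wise level (default 0.05).
#' @return A list: `m_eff` (integer), `bonferroni`, `eigenvalues`.
#' @examples
#' effective_tests(matrix(rnorm(500), 100, 5))$m_eff  # close to 5
#' @export
effective_tests <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2L) abort("need at least 2 traits")
  if (nrow(scores) < 3L) abort("need at least 3 individuals")
  sds <- apply(scores, 2, stats::sd)
  if (any(sds < .Machine$double.eps)) {
    warn(sprintf("%d constant trait score(s) dropped", sum(sds < .Machine$double.eps)))
    scores <- scores[, sds >= .Machine$double.eps, drop = FALSE]
  }
  lam <- eigen(stats::cor(scores), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  m_eff <- as.integer(round(sum((lam >= 1) + (lam - floor(lam)))))
  m_eff <- max(1L, m_eff)
  list(m_eff = m_eff, bonferroni = alpha / m_eff, eigenvalues = lam)
}

#' @rdname fit_traits
#' @param x An `endo_traits` object.
#' @param ... Ignored.
#' @export
tidy.endo_traits <- function(x, ...) {
  dplyr::select(as_tibble(x), "segment_id", "k", "r2", "p_perm")
}

#' @rdname fit_traits
#' @export
glance.endo_traits <- function(x, ...) {
  tibble(n_traits = nrow(x),
         n_nominal = sum(x$p_perm < 0.05),
         median_r2 = stats::median(x$r2),
         min_p = min(x$p_perm))
}
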