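#' Build a synthetic symmetric landmark template
#'
#' Constructs a face-like half-ellipsoid lattice of `p` landmarks that is
#' mirror-symmetric across the sagittal plane (x = 0), together with the
#' left/right pairing map that real dense facial templates carry. Midline
#' landmarks pair with themselves; every off-midline landmark pairs with its
#' mirror image. The template stands in for an anthropometric facial mask so
#' that symmetrization, alignment and segmentation can be exercised at any
#' desk-scale `p`.
#'
#' @param p Number of landmarks (>= 20).
#' @param seed Integer seed; controls a small symmetric jitter that breaks
#'   lattice regularity without breaking symmetry.
#' @param jitter_sd Standard deviation of the jitter, in template units
#'   (the face spans roughly 2 units).
#'
#' @return An object of class `endo_template`: a list with `coords`
#'   (p x 3 matrix, dimnames x/y/z), `pair_map` (integer involution of
#'   `1:p`), and `p`.
#' @examples
#' tpl <- make_template(p = 100, seed = 1)
#' all(tpl$pair_map[tpl$pair_map] == seq_len(tpl$p))
#' @export
make_template <- function(p = 250, seed = 1, jitter_sd = 0.01) {
  p <- check_count(p, 20L, "p")
  seed <- check_count(seed, 0L, "seed")

  # p = n_mid (midline) + 2 * n_side; keep a short midline profile and
  # match parity so the count lands exactly on p
  n_mid <- if (p %% 2L == 0L) 6L else 7L
  n_side <- (p - n_mid) %/% 2L
  if (n_side < 5L) abort("`p` too small to form the lattice")

  # midline profile: points on the x = 0 arc of the half ellipsoid
  t_mid <- seq(-0.9, 0.9, length.out = n_mid)
  mid <- cbind(x = 0, y = t_mid, z = 0.6 * sqrt(pmax(0, 1 - t_mid^2)))

  # one side: sunflower (Fibonacci) layout over the quarter-disk u in (0,1],
  # v in (-1,1), lifted onto the ellipsoid z = c * sqrt(1 - u^2 - v^2)
  golden <- (sqrt(5) - 1) / 2
  k <- seq_len(n_side)
  r <- sqrt((k - 0.5) / n_side)
  th <- 2 * pi * golden * k
  u <- 0.05 + 0.90 * r * abs(cos(th))          # x > 0 strictly
  v <- 0.95 * r * sin(th)
  w2 <- pmax(0, 1 - u^2 - v^2)
  side <- cbind(x = u, y = v, z = 0.6 * sqrt(w2))

  coords <- rbind(mid, side, side %*% diag(c(-1, 1, 1)))
  pair_map <- c(seq_len(n_mid),
                n_mid + n_side + seq_len(n_side),
                n_mid + seq_len(n_side))

  # symmetric jitter: midline jittered in (y, z) only; right-side jitter
  # mirrored onto the left so reflect-then-permute stays the identity
  set.seed(seed)
  jm <- cbind(0, matrix(stats::rnorm(2L * n_mid, 0, jitter_sd), n_mid, 2))
  js <- matrix(stats::rnorm(3L * n_side, 0, jitter_sd), n_side, 3)
  coords <- coords + rbind(jm, js, js %*% diag(c(-1, 1, 1)))

  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, pair_map = as.integer(pair_map), p = p),
            class = "endo_template")
}

#' @export
print.endo_template <- function(x, ...) {
  cat(sprintf("<endo_template> %d landmarks (%d midline), symmetric across x = 0\n",
              x$p, sum(x$pair_map == seq_len(x$p))))
  invisible(x)
}

#' Unit direction of effect localized on a patch of the template
#'
#' Builds a 3p-dimensional unit vector that displaces landmarks near a
#' template point (Gaussian falloff), symmetrically on both sides of the
#' face. Used to plant a known group shape difference in simulated cohorts.
#'
#' @param template An `endo_template`.
#' @param center Index of the landmark the patch is centered on (its mirror
#'   partner is used for the other side).
#' @param bandwidth Gaussian falloff scale in template units.
#' @param axis Displacement axis, length-3; default displaces outward in z.
#' @return Unit numeric vector of length 3p, landmark-major (x1, y1, z1, ...).
#' @export
localized_direction <- function(template, center = 1L, bandwidth = 0.35,
                                axis = c(0, 0, 1)) {
  stopifnot(inherits(template, "endo_template"))
  ctr <- template$coords[center, ]
  ctr2 <- template$coords[template$pair_map[center], ]
  d2 <- rowSums(sweep(template$coords, 2, ctr)^2)
  d2b <- rowSums(sweep(template$coords, 2, ctr2)^2)
  w <- exp(-d2 / (2 * bandwidth^2)) + exp(-d2b / (2 * bandwidth^2))
  disp <- outer(w, axis / sqrt(sum(axis^2)))
  unit_vector(flatten_config(disp))
}
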