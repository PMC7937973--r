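#' Reflect a landmark configuration across the sagittal plane
#'
#' Negates the x coordinate and re-indexes the landmarks through the
#' template's left/right pairing map, so each left landmark becomes its
#' right homologue and landmark identity is preserved. Applied twice it is
#' the identity.
#'
#' @param coords p x 3 landmark matrix.
#' @param pair_map Integer involution of `1:p` pairing mirror landmarks.
#' @return Reflected p x 3 matrix.
#' @export
reflect_landmarks <- function(coords, pair_map) {
  p <- nrow(coords)
  if (length(pair_map) != p) abort("`pair_map` length must equal the landmark count")
  if (!all(sort(pair_map) == seq_len(p)) || !all(pair_map[pair_map] == seq_len(p)))
    abort("`pair_map` must be an involution of 1..p")
  refl <- coords %*% diag(c(-1, 1, 1))
  refl <- refl[pair_map, , drop = FALSE]
  dimnames(refl) <- dimnames(coords)
  refl
}

#' Symmetrize a configuration against its reflection
#'
#' Co-superimposes the original and its reflection onto their joint
#' Procrustes mean (rotation and translation only, no scaling between the
#' pair) and averages them pointwise. The result is a fixed point of
#' [reflect_landmarks()] up to alignment.
#'
#' @param original,reflected p x 3 matrices with corresponding landmarks.
#' @param align If `FALSE`, skip the pairwise superimposition and average
#'   as-is (the two are assumed already in one frame).
#' @return Symmetric p x 3 configuration.
#' @export
symmetrize_landmarks <- function(original, reflected, align = TRUE) {
  if (!all(dim(original) == dim(reflected))) abort("shape mismatch")
  if (align) {
    g <- gpa(list(original, reflected), remove_scale = FALSE, canonical = FALSE)
    original <- unflatten_config(g$shapes[1, ])
    reflected <- unflatten_config(g$shapes[2, ])
  }
  (original + reflected) / 2
}

# rotate (and optionally scale) configuration X onto Y; both centered.
# Proper rotation only: reflections are handled by the pairing map upstream.
procrustes_rotation <- function(X, Y) {
  s <- svd(crossprod(Y, X))
  d <- sign(det(s$u %*% t(s$v)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

# superimpose config onto target: center, optional scale to target's
# centroid size, rotate. Returns the aligned p x 3 matrix.
superimpose <- function(config, target, scale = TRUE) {
  Xc <- sweep(config, 2, colMeans(config))
  Yc <- sweep(target, 2, colMeans(target))
  if (scale) Xc <- Xc * (sqrt(sum(Yc^2)) / sqrt(sum(Xc^2)))
  Xc %*% procrustes_rotation(Xc, Yc)
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Iteratively centers, optionally scales to unit centroid size, and
#' rotates every configuration onto the running consensus until the
#' consensus stabilizes, removing position, orientation and (optionally)
#' scale. Rotations are proper; mirror symmetry is handled explicitly by
#' the pairing map in [reflect_landmarks()], never by improper rotations.
#'
#' @param configs List of p x 3 matrices, or an n x p x 3 array.
#' @param remove_scale Scale each configuration to unit centroid size
#'   (default `TRUE`). Centroid sizes are always returned so facial size
#'   can be used as a covariate.
#' @param tol Convergence tolerance on the consensus root-mean-square
#'   change.
#' @param max_iter Iteration cap.
#' @param canonical Rotate the converged solution onto the consensus
#'   principal axes (stable sign convention), making the output frame
#'   independent of the inputs' initial orientation (default `TRUE`). Set
#'   `FALSE` to stay in the inputs' frame, e.g. when the coordinate axes
#'   carry meaning such as the sagittal mirror plane at x = 0.
#' @return An `endo_aligned` list: `shapes` (n x 3p matrix of flattened
#'   aligned configurations), `consensus` (p x 3), `centroid_sizes`
#'   (length n), `iterations`, `rss_path` (sum of squared distances to the
#'   consensus per iteration, non-increasing).
#' @examples
#' tpl <- make_template(60, seed = 2)
#' co <- simulate_cohort(tpl, n = 12, seed = 3)
#' al <- gpa(co$configs)
#' max(abs(colMeans(unflatten_config(al$shapes[1, ]))))  # centered
#' @export
gpa <- function(configs, remove_scale = TRUE, tol = 1e-8, max_iter = 100,
                canonical = TRUE) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[1]), function(i) configs[i, , ])
  n <- length(configs)
  if (n < 2L) abort("need at least 2 configurations")
  p <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 1L) == p)) abort("configurations differ in p")

  sizes <- vapply(configs, centroid_size, 1)
  if (any(sizes < .Machine$double.eps))
    abort("degenerate configuration: all landmarks coincident")

  aligned <- lapply(seq_len(n), function(i) {
    Xc <- sweep(configs[[i]], 2, colMeans(configs[[i]]))
    if (remove_scale) Xc / sizes[i] else Xc
  })

  consensus <- Reduce(`+`, aligned) / n
  rss_path <- numeric(0)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(Xc) Xc %*% procrustes_rotation(Xc, consensus))
    new_consensus <- Reduce(`+`, aligned) / n
    if (remove_scale) new_consensus <- new_consensus / centroid_size(new_consensus)
    rss_path <- c(rss_path,
                  sum(vapply(aligned, function(Xc) sum((Xc - new_consensus)^2), 1)))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }

  if (canonical) {
    # rotate everything onto the consensus principal axes (stable sign
    # convention), so the output frame does not depend on the inputs'
    # initial orientation
    V <- svd(consensus)$v
    W <- consensus %*% V      # canonical coordinates; sign-fix on these
    for (j in 1:3) V[, j] <- V[, j] * sign(W[which.max(abs(W[, j])), j])
    if (det(V) < 0) V[, 3] <- -V[, 3]
    aligned <- lapply(aligned, function(Xc) Xc %*% V)
    consensus <- consensus %*% V
  }

  shapes <- do.call(rbind, lapply(aligned, flatten_config))
  structure(list(shapes = shapes, consensus = consensus,
                 centroid_sizes = sizes, iterations = it,
                 rss_path = rss_path),
            class = "endo_aligned")
}

#' @export
print.endo_aligned <- function(x, ...) {
  cat(sprintf("<endo_aligned> %d configurations x %d landmarks, %d GPA iterations\n",
              nrow(x$shapes), ncol(x$shapes) / 3, x$iterations))
  invisible(x)
}

#' Symmetrize and align a whole cohort
#'
#' Convenience wrapper running the standard preprocessing: each
#' configuration is reflected through the pairing map, co-superimposed with
#' its reflection and averaged ([symmetrize_landmarks()]), then all
#' symmetric configurations are jointly aligned by [gpa()].
#'
#' @param configs n x p x 3 array or list of p x 3 matrices.
#' @param pair_map Template pairing involution.
#' @inheritParams gpa
#' @return An `endo_aligned` object (see [gpa()]).
#' @export
prep_cohort <- function(configs, pair_map, remove_scale = TRUE) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[1]), function(i) configs[i, , ])
  symm <- lapply(configs, function(cf)
    symmetrize_landmarks(cf, reflect_landmarks(cf, pair_map)))
  gpa(symm, remove_scale = remove_scale)
}
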