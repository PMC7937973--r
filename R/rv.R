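#' Escoufier's RV coefficient between two variable blocks
#'
#' The RV coefficient generalizes squared correlation to two blocks of
#' variables measured on the same individuals:
#' `RV = tr(Sxy Syx) / sqrt(tr(Sxx^2) tr(Syy^2))` with `S` the
#' cross-product matrices of the column-centered blocks. It is 1 when one
#' block is an orthogonal transform of the other and approaches 0 for
#' independent blocks.
#'
#' @param X,Y Numeric matrices with the same number of rows (individuals);
#'   centered internally.
#' @return A scalar in `[0, 1]`.
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' rv_coefficient(X, X)  # 1
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("blocks must share individuals")
  if (nrow(X) < 3L) abort("need at least 3 individuals")
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  sxx <- sum(crossprod(Xc)^2); syy <- sum(crossprod(Yc)^2)
  if (sxx < .Machine$double.eps || syy < .Machine$double.eps)
    abort("zero-variance block")
  sum(crossprod(Xc, Yc)^2) / sqrt(sxx * syy)
}

#' Landmark-landmark RV similarity matrix
#'
#' Computes the p x p matrix of RV coefficients between the 3-column
#' coordinate blocks of every landmark pair, from a matrix of flattened
#' aligned shapes. This is the structural similarity that drives the
#' data-driven facial segmentation. Landmarks with (numerically) zero
#' variance are excluded with a warning.
#'
#' @param shapes n x 3p matrix of flattened aligned (and typically
#'   covariate-adjusted) configurations, landmark-major (x1, y1, z1, ...).
#' @return An `endo_similarity` list: `values` (p x p, symmetric, unit
#'   diagonal), `landmark_ids` (indices retained).
#' @export
build_similarity <- function(shapes) {
  shapes <- as.matrix(shapes)
  q <- ncol(shapes)
  if (q %% 3L != 0L) abort("`shapes` must have 3p columns")
  p <- q %/% 3L
  Xc <- scale(shapes, scale = FALSE)
  C2 <- crossprod(Xc)^2                       # squared cross-products
  E <- matrix(0, q, p); E[cbind(seq_len(q), rep(seq_len(p), each = 3L))] <- 1
  B <- t(E) %*% C2 %*% E                      # B[i,j] = ||Sij||_F^2
  diagB <- diag(B)
  keep <- which(diagB > .Machine$double.eps)
  if (length(keep) < p)
    warn(sprintf("%d zero-variance landmark(s) excluded", p - length(keep)))
  B <- B[keep, keep, drop = FALSE]
  vals <- B / sqrt(outer(diag(B), diag(B)))
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  structure(list(values = vals, landmark_ids = keep),
            class = "endo_similarity")
}

#' @export
print.endo_similarity <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<endo_similarity> %d landmarks; off-diagonal RV median %.3f\n",
              nrow(x$values), stats::median(off)))
  invisible(x)
}
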