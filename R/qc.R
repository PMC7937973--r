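#' Outlier QC by Mahalanobis distance in a reduced shape space
#'
#' Scores each aligned shape by its Mahalanobis distance to the sample mean,
#' computed in a PCA-reduced space (so the covariance is invertible), and
#' standardizes the distances to Z-scores. Individuals whose Z-score exceeds
#' `z_threshold`, or whose externally supplied missingness exceeds
#' `miss_threshold`, are flagged for inspection.
#'
#' @param aligned An [gpa()] result, or an n x q shape matrix.
#' @param z_threshold Flagging threshold on the distance Z-score (default 2,
#'   the conventional "check by hand" level).
#' @param reduced_dim Dimension of the PCA space for the Mahalanobis
#'   computation; default keeps components covering `var_explained` of the
#'   variance. Must be `< n`.
#' @param var_explained Variance fraction used when `reduced_dim` is `NULL`.
#' @param missingness Optional per-individual missingness fraction in
#'   `[0, 1]` (0 when landmarks are fully observed).
#' @param miss_threshold Missingness flagging threshold.
#' @return A tibble with columns `id`, `mahalanobis`, `z_score`,
#'   `missingness`, `flag`.
#' @export
qc_scores <- function(aligned, z_threshold = 2, reduced_dim = NULL,
                      var_explained = 0.98, missingness = NULL,
                      miss_threshold = 0.2) {
  shapes <- if (inherits(aligned, "endo_aligned")) aligned$shapes else as.matrix(aligned)
  n <- nrow(shapes)
  pc <- stats::prcomp(shapes, center = TRUE, scale. = FALSE)
  pos <- which(pc$sdev^2 > 1e-12 * pc$sdev[1]^2)
  if (is.null(reduced_dim)) {
    cum <- cumsum(pc$sdev[pos]^2) / sum(pc$sdev[pos]^2)
    reduced_dim <- which(cum >= var_explained)[1]
  }
  reduced_dim <- min(reduced_dim, length(pos), n - 2L)
  if (reduced_dim >= n) abort("`reduced_dim` must be smaller than n")
  Z <- pc$x[, seq_len(reduced_dim), drop = FALSE]
  # principal axes are uncorrelated: Mahalanobis = scaled Euclidean
  d <- sqrt(rowSums(sweep(Z, 2, pc$sdev[seq_len(reduced_dim)], "/")^2))
  z <- (d - mean(d)) / stats::sd(d)
  if (is.null(missingness)) missingness <- rep(0, n)
  tibble(id = seq_len(n), mahalanobis = d, z_score = z,
         missingness = missingness,
         flag = z > z_threshold | missingness > miss_threshold)
}
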