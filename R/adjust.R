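# NIPALS PLS2: Y (n x q) on X (n x c), both centered internally.
# Returns the fitted Y-effect of X (on the centered scale) plus the means,
# so callers can residualize. With ncomp = rank(X) the fit equals ordinary
# least squares on X.
pls_fit <- function(X, Y, ncomp, tol = 1e-12, max_iter = 500) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2, xm); F <- sweep(Y, 2, ym)
  n <- nrow(E)
  W <- matrix(0, ncol(X), ncomp); P <- matrix(0, ncol(X), ncomp)
  Q <- matrix(0, ncol(Y), ncomp); TT <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- F[, which.max(colSums(F^2)), drop = FALSE]
    if (sum(u^2) < .Machine$double.eps) break
    w_old <- NULL
    for (i in seq_len(max_iter)) {
      w <- crossprod(E, u); w <- w / sqrt(sum(w^2))
      t_ <- E %*% w
      q <- crossprod(F, t_) / sum(t_^2)
      u <- F %*% q / sum(q^2)
      if (!is.null(w_old) && sum((w - w_old)^2) < tol) break
      w_old <- w
    }
    t_ <- E %*% w
    p_ <- crossprod(E, t_) / sum(t_^2)
    q <- crossprod(F, t_) / sum(t_^2)
    E <- E - t_ %*% t(p_)
    F <- F - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; TT[, a] <- t_
  }
  used <- which(colSums(TT^2) > 0)
  list(scores = TT[, used, drop = FALSE], x_weights = W[, used, drop = FALSE],
       x_loadings = P[, used, drop = FALSE], y_loadings = Q[, used, drop = FALSE],
       fitted_centered = TT[, used, drop = FALSE] %*% t(Q[, used, drop = FALSE]),
       x_mean = xm, y_mean = ym, ncomp = length(used))
}

#' Remove covariate effects from shape variables by PLSR
#'
#' Fits a partial least squares regression of the shape matrix on the
#' covariates (one component per covariate by default, capped at the
#' covariate rank) and returns the shapes minus the fitted covariate
#' effect, keeping the grand mean. With the full component count on
#' full-rank covariates this equals least-squares residualization, so the
#' residual columns are uncorrelated with every covariate.
#'
#' @param shapes n x q numeric matrix (rows = individuals); typically the
#'   `shapes` slot of [gpa()].
#' @param covariates n x c numeric matrix or data frame of covariates
#'   (e.g. sex, age, height, weight, centroid size); centered internally.
#' @param ncomp Number of PLS components; default `ncol(covariates)`,
#'   silently capped at the covariate matrix rank (a warning reports any
#'   cap).
#' @return Matrix of the same dimension as `shapes`: residual shapes with
#'   the grand mean added back. The fitted effect is attached as attribute
#'   `"fitted_effect"`.
#' @export
adjust_covariates <- function(shapes, covariates, ncomp = NULL) {
  shapes <- as.matrix(shapes)
  covariates <- as.matrix(as.data.frame(covariates))
  storage.mode(covariates) <- "double"
  if (nrow(shapes) != nrow(covariates)) abort("row mismatch")
  if (nrow(shapes) <= ncol(covariates))
    abort("need more individuals than covariates")
  rk <- qr(scale(covariates, scale = FALSE))$rank
  if (is.null(ncomp)) ncomp <- ncol(covariates)
  if (ncomp > rk) {
    warn(sprintf("covariates have rank %d; components capped from %d", rk, ncomp))
    ncomp <- rk
  }
  fit <- pls_fit(covariates, shapes, ncomp = ncomp)
  res <- shapes - fit$fitted_centered
  attr(res, "fitted_effect") <- fit$fitted_centered
  res
}
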