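#' Fit a per-segment shape model (GPA + PCA with parallel analysis)
#'
#' Extracts a segment's landmarks from every aligned configuration,
#' re-superimposes them by a fresh GPA (position, orientation, scale), and
#' fits a PCA on the re-aligned coordinates. The retained dimension `k` is
#' chosen by Horn's parallel analysis: eigenvalues must exceed the chosen
#' percentile of eigenvalues from null datasets whose raw segment
#' coordinates are independently column-permuted — destroying
#' inter-landmark covariance while preserving marginals — and which are
#' then pushed through the same Procrustes superimposition, so the null
#' spectrum carries the same alignment constraints as the observed one
#' (a plain column permutation of aligned coordinates grossly over-retains,
#' because superimposition concentrates isotropic variance in 3m - 7
#' dimensions).
#'
#' @param shapes n x 3p matrix of flattened aligned configurations (after
#'   covariate adjustment).
#' @param hierarchy An [spectral_hierarchy()] object.
#' @param segment_id Segment to model.
#' @param pa_reps Number of permuted datasets (default 100).
#' @param pa_percentile Percentile of the permuted eigenvalue distribution
#'   (default 0.95).
#' @param seed Seed for the permutations.
#' @param max_k Optional cap on the retained dimension.
#' @return An `endo_segmodel` list: `segment_id`, `landmarks`, `mean_shape`
#'   (m x 3), `basis` (orthonormal 3m x k), `eigenvalues` (nonincreasing,
#'   length k), `k`, `total_variance`.
#' @export
fit_segment_model <- function(shapes, hierarchy, segment_id,
                              pa_reps = 100, pa_percentile = 0.95,
                              seed = 1, max_k = NULL) {
  stopifnot(inherits(hierarchy, "endo_hierarchy"))
  idx <- segment_landmarks(hierarchy, segment_id)
  if (length(idx) < 3L) abort("segment has fewer than 3 landmarks")
  n <- nrow(shapes)
  if (n < 10L) abort("need at least 10 individuals")

  seg <- shapes[, coord_columns(idx), drop = FALSE]
  configs <- lapply(seq_len(n), function(i) unflatten_config(seg[i, ]))
  al <- gpa(configs, remove_scale = TRUE)

  X <- al$shapes
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k_all <- sum(ev > 1e-12 * ev[1])

  set.seed(seed)
  perm_ev <- matrix(NA_real_, pa_reps, k_all)
  for (r in seq_len(pa_reps)) {
    segp <- apply(seg, 2, sample)
    # a loosely converged superimposition is enough for the null spectrum
    alp <- gpa(lapply(seq_len(n), function(i) unflatten_config(segp[i, ])),
               remove_scale = TRUE, tol = 1e-4, max_iter = 5)
    Xp <- scale(alp$shapes, scale = FALSE)
    evp <- svd(Xp, nu = 0, nv = 0)$d^2 / (n - 1)
    perm_ev[r, ] <- evp[seq_len(k_all)]
  }
  thresh <- apply(perm_ev, 2, stats::quantile, probs = pa_percentile)
  exceeds <- ev[seq_len(k_all)] > thresh
  k <- if (any(!exceeds)) which.min(exceeds) - 1L else k_all
  if (!is.null(max_k)) k <- min(k, max_k)
  if (k == 0L)
    abort(sprintf(
      "segment %d: no component exceeds the parallel-analysis threshold (top eigenvalue %.3g vs null %.3g)",
      segment_id, ev[1], thresh[1]))

  structure(list(segment_id = segment_id, landmarks = idx,
                 mean_shape = al$consensus,
                 basis = pc$rotation[, seq_len(k), drop = FALSE],
                 eigenvalues = ev[seq_len(k)], k = k,
                 total_variance = sum(ev)),
            class = "endo_segmodel")
}

#' @export
print.endo_segmodel <- function(x, ...) {
  cat(sprintf("<endo_segmodel> segment %d: %d landmarks, k = %d (%.1f%% variance)\n",
              x$segment_id, length(x$landmarks), x$k,
              100 * sum(x$eigenvalues) / x$total_variance))
  invisible(x)
}

#' Project configurations into a segment's PC space
#'
#' Extracts the segment's landmarks from each configuration, superimposes
#' them onto the model's mean shape (removing position, orientation and
#' scale), centers at the mean and projects onto the model basis. Because
#' all faces share one template, any configuration can be scored in any
#' segment model. Scores are invariant to rigid motion and scaling of the
#' input face.
#'
#' @param model An [fit_segment_model()] object.
#' @param configs A single p x 3 configuration, an n x p x 3 array, or an
#'   n x 3p matrix of flattened configurations.
#' @param align Superimpose each segment onto the model mean before
#'   projecting (default). With `align = FALSE` the input is taken to be in
#'   the model's frame already and the projection is purely linear; use
#'   this when scoring shapes reconstructed directly in model space, since
#'   the similarity superimposition re-scales large synthetic deformations.
#' @return n x k matrix of PC scores (a 1 x k matrix for a single
#'   configuration).
#' @export
project_segment <- function(model, configs, align = TRUE) {
  stopifnot(inherits(model, "endo_segmodel"))
  if (is.matrix(configs) && ncol(configs) == 3L)
    configs <- array(configs, dim = c(1L, nrow(configs), 3L))
  if (is.matrix(configs)) {
    n <- nrow(configs)
    configs <- array(
      vapply(seq_len(n), function(i) unflatten_config(configs[i, ]),
             matrix(0, ncol(configs) / 3L, 3L)),
      dim = c(ncol(configs) / 3L, 3L, n))
    configs <- aperm(configs, c(3, 1, 2))
  }
  n <- dim(configs)[1]
  m <- length(model$landmarks)
  # a segment-frame input (already just this segment's landmarks) passes
  # through; a full-template input has the segment extracted
  seg_idx <- if (dim(configs)[2] == m && any(model$landmarks > m))
    seq_len(m) else model$landmarks
  mu <- flatten_config(model$mean_shape)
  out <- matrix(NA_real_, n, model$k)
  for (i in seq_len(n)) {
    cf <- configs[i, seg_idx, , drop = TRUE]
    if (!all(is.finite(cf))) abort("non-finite coordinates")
    al <- if (align) superimpose(cf, model$mean_shape, scale = TRUE) else cf
    out[i, ] <- (flatten_config(al) - mu) %*% model$basis
  }
  out
}
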