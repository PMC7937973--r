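#' Hierarchical spectral segmentation of the landmark similarity matrix
#'
#' Builds a global-to-local hierarchy of facial segments by recursive
#' normalized-cut bisection: for the current segment, the normalized
#' Laplacian `L = I - D^{-1/2} S D^{-1/2}` of its similarity submatrix is
#' formed, landmarks are embedded on the Fiedler vector (eigenvector of the
#' second-smallest eigenvalue), and split by seeded 2-means on that
#' embedding. Running `levels` bisection rounds below the full face yields
#' `2^(levels+1) - 1` segments in total; at the conventional depth of five
#' levels that is 63 segments, the whole face being segment 1.
#'
#' @param sim An [build_similarity()] object, or a symmetric p x p
#'   similarity matrix with unit diagonal.
#' @param levels Number of bisection rounds below the root (default 5).
#' @param seed Integer seed for the 2-means step (10 restarts).
#' @param min_size Smallest leaf segment allowed (default 3). Feasibility
#'   is enforced depth-aware: a split whose 2-means solution would starve
#'   the remaining subtree falls back to a median split on the Fiedler
#'   embedding, and a segment genuinely too small to split raises an error
#'   naming it.
#' @return An `endo_hierarchy` object: tibble `segments` with columns
#'   `segment_id` (breadth-first, root = 1), `level` (0 = full face),
#'   `parent` (NA for the root), `size`, and list-column `landmarks`.
#' @examples
#' s <- diag(10); s[1:5, 1:5] <- 0.9; s[6:10, 6:10] <- 0.9; diag(s) <- 1
#' h <- spectral_hierarchy(s, levels = 1)
#' nrow(h$segments)  # 3
#' @export
spectral_hierarchy <- function(sim, levels = 5, seed = 1, min_size = 3) {
  S <- if (inherits(sim, "endo_similarity")) sim$values else as.matrix(sim)
  ids <- if (inherits(sim, "endo_similarity")) sim$landmark_ids else seq_len(nrow(S))
  if (!isSymmetric(unname(S), tol = 1e-8)) abort("similarity must be symmetric")
  levels <- check_count(levels, 1L, "levels")
  p <- nrow(S)

  n_segments <- 2^(levels + 1) - 1
  members <- vector("list", n_segments)
  members[[1]] <- seq_len(p)
  seg_level <- integer(n_segments)
  parent <- rep(NA_integer_, n_segments)

  if (p < min_size * 2^levels)
    abort(sprintf("%d landmarks cannot sustain %d levels (need >= %d)",
                  p, levels, min_size * 2^levels))

  set.seed(seed)
  for (sid in seq_len(2^levels - 1)) {
    idx <- members[[sid]]
    # each child must still support its own remaining subtree
    child_min <- min_size * 2^(levels - seg_level[sid] - 1L)
    if (length(idx) < 2L * child_min)
      abort(sprintf("segment %d (%d landmarks) is too small to split", sid, length(idx)))
    grp <- bisect_spectral(S[idx, idx, drop = FALSE], min_size = child_min)
    kids <- c(2L * sid, 2L * sid + 1L)
    members[[kids[1]]] <- idx[grp == 1L]
    members[[kids[2]]] <- idx[grp == 2L]
    seg_level[kids] <- seg_level[sid] + 1L
    parent[kids] <- sid
  }

  structure(list(
    segments = tibble(segment_id = seq_len(n_segments),
                      level = seg_level, parent = parent,
                      size = lengths(members),
                      landmarks = lapply(members, function(m) ids[m])),
    levels = levels, p = p),
    class = "endo_hierarchy")
}

# one normalized-cut bisection; returns 1/2 labels with both sides >= min_size
bisect_spectral <- function(S, min_size, nstart = 10) {
  m <- nrow(S)
  d <- rowSums(S)
  d[d < .Machine$double.eps] <- .Machine$double.eps
  Dis <- 1 / sqrt(d)
  L <- diag(m) - (Dis * S) * rep(Dis, each = m)   # D^-1/2 S D^-1/2 scaling
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  fiedler <- ev$vectors[, m - 1L]                 # second-smallest eigenvalue
  grp <- tryCatch(
    stats::kmeans(fiedler, centers = 2L, nstart = nstart)$cluster,
    error = function(e) rep(0L, m))   # degenerate embedding: fall through
  # force a feasible split if 2-means ran degenerate on a tight embedding
  if (length(unique(grp)) < 2L || min(table(grp)) < min_size) {
    ord <- order(fiedler)
    grp <- integer(m)
    grp[ord[seq_len(m %/% 2L)]] <- 1L
    grp[grp == 0L] <- 2L
  }
  # deterministic labeling: cluster containing the smallest landmark index is 1
  if (grp[1] == 2L) grp <- 3L - grp
  grp
}

#' Landmark members of one segment
#' @param hierarchy An [spectral_hierarchy()] object.
#' @param segment_id Segment number (root = 1).
#' @return Integer vector of landmark indices.
#' @export
segment_landmarks <- function(hierarchy, segment_id) {
  stopifnot(inherits(hierarchy, "endo_hierarchy"))
  hierarchy$segments$landmarks[[segment_id]]
}

#' @export
print.endo_hierarchy <- function(x, ...) {
  cat(sprintf("<endo_hierarchy> %d segments over %d levels (%d landmarks)\n",
              nrow(x$segments), x$levels, x$p))
  invisible(x)
}

#' @rdname spectral_hierarchy
#' @param x An `endo_hierarchy`.
#' @param ... Ignored.
#' @export
tidy.endo_hierarchy <- function(x, ...) {
  dplyr::select(x$segments, "segment_id", "level", "parent", "size")
}
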