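#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# flatten an n x p x 3 array of configurations to n x 3p (x1,y1,z1,x2,...)
flatten_configs <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 3L)
  n <- dim(arr)[1]; p <- dim(arr)[2]
  out <- matrix(NA_real_, n, 3L * p)
  for (d in 1:3) out[, seq(d, 3L * p, by = 3L)] <- arr[, , d]
  out
}

# inverse of flatten_configs for a single configuration
unflatten_config <- function(v) {
  p <- length(v) / 3L
  matrix(v, nrow = p, ncol = 3L, byrow = TRUE)
}

flatten_config <- function(coords) as.vector(t(coords))

# column indices of landmark set `idx` in a flattened 3p vector
coord_columns <- function(idx) {
  as.vector(t(outer(idx - 1L, 1:3, function(i, d) 3L * i + d)))
}

centroid_size <- function(coords) {
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, ctr)^2))
}

check_count <- function(x, min, name) {
  if (!is.numeric(x) || length(x) != 1L || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

unit_vector <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort("cannot normalize a zero vector")
  v / nv
}

angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(1, ca)) * 180 / pi
}
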