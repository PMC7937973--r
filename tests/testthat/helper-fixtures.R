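# Shared small fixtures, built in code at load time.

fix_template <- make_template(p = 100, seed = 11)

# a prepped, adjusted cohort reused by segmentation/trait tests
fix_cohort <- simulate_cohort(fix_template, n = 80, seed = 12)
fix_aligned <- prep_cohort(fix_cohort$configs, fix_template$pair_map)
fix_shapes <- adjust_covariates(
  fix_aligned$shapes,
  cbind(as.matrix(fix_cohort$covariates[, c("sex", "age", "height", "weight")]),
        size = fix_aligned$centroid_sizes))

# random 3D rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# exhaustive permutation p-value for the group-contrast R2 at tiny n
exact_perm_p <- function(pc, group) {
  n1 <- sum(group == 1)
  Yc <- scale(pc, scale = FALSE)
  r2_of <- function(g) {
    gc <- g - mean(g)
    sum(crossprod(Yc, gc)^2) / sum(gc^2) / sum(Yc^2)
  }
  obs <- r2_of(group)
  sets <- utils::combn(length(group), n1)
  perms <- apply(sets, 2, function(ix) {
    g <- rep(0, length(group)); g[ix] <- 1
    r2_of(g)
  })
  mean(perms >= obs - 1e-12)
}
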