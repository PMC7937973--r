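test_that("one-component PLSR contrast equals the oriented group-mean difference", {
  set.seed(41)
  # mean difference planted exactly along the first PC axis
  n <- 60
  g <- rep(0:1, each = n / 2)
  pc <- matrix(rnorm(n * 4, 0, 0.3), n, 4)
  pc[g == 1, 1] <- pc[g == 1, 1] + 2
  ct <- plsr_contrast(pc, g)
  expect_equal(sum(ct$direction^2), 1)
  expect_gt(ct$direction[1], 0.99)           # +e1, oriented toward group 1

  # algebraic oracle: direction parallel to the difference of group means
  for (s in 1:5) {
    set.seed(s)
    pc2 <- matrix(rnorm(50 * 6), 50, 6)
    g2 <- rbinom(50, 1, 0.5)
    if (length(unique(g2)) < 2) next
    d_oracle <- colMeans(pc2[g2 == 1, , drop = FALSE]) -
      colMeans(pc2[g2 == 0, , drop = FALSE])
    d_oracle <- d_oracle / sqrt(sum(d_oracle^2))
    ct2 <- plsr_contrast(pc2, g2)
    expect_lt(acos(pmin(1, sum(ct2$direction * d_oracle))), 1e-6)
  }

  # swapping the labels flips the direction (orientation follows group 1)
  cts <- plsr_contrast(pc, 1 - g)
  expect_equal(cts$direction, -ct$direction)
  expect_equal(cts$r2, ct$r2)

  # identical group distributions: r2 near zero
  nulls <- vapply(1:40, function(s) {
    set.seed(s)
    plsr_contrast(matrix(rnorm(400 * 3), 400, 3), rep(0:1, 200))$r2
  }, 1)
  expect_gte(mean(nulls < 0.02), 0.95)

  expect_error(plsr_contrast(pc, rep(1, n)), "group")
  expect_error(plsr_contrast(matrix(0, 10, 2), rep(0:1, 5)), "covariance")
})

test_that("permutation p-values match exhaustive enumeration and the boundary rule", {
  set.seed(42)
  pc <- matrix(rnorm(18), 6, 3)
  g <- c(0, 0, 0, 1, 1, 1)
  pt <- permutation_test(pc, g, n_perm = 4999, seed = 7)
  p_exact <- exact_perm_p(pc, g)
  expect_lt(abs(pt$p_perm - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4999) + 1e-3)

  # a contrast stronger than every permutation hits the add-one floor
  pc2 <- matrix(rnorm(40 * 2, 0, 0.01), 40, 2)
  g2 <- rep(0:1, each = 20)
  pc2[g2 == 1, 1] <- pc2[g2 == 1, 1] + 5
  pt2 <- permutation_test(pc2, g2, n_perm = 199, seed = 8)
  expect_equal(pt2$p_perm, 1 / 200)

  expect_error(permutation_test(pc, g, n_perm = 50), "n_perm")
  expect_error(permutation_test(pc, rep(0, 6)), "constant")
})

test_that("null permutation p-values are uniform", {
  ps <- vapply(1:120, function(s) {
    set.seed(1000 + s)
    permutation_test(matrix(rnorm(30 * 3), 30, 3), rep(0:1, 15),
                     n_perm = 199, seed = s)$p_perm
  }, 1)
  # permutation p-values are discrete, so ties are expected; the KS test
  # is still a sound calibration check at this resolution
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("trait selection keeps nominal hits and recovers planted segments", {
  tr <- tibble::tibble(segment_id = 1:3, p_perm = c(0.01, 0.04, 0.06))
  expect_equal(select_traits(tr, alpha = 0.05)$segment_id, 1:2)
  expect_equal(nrow(select_traits(tibble::tibble(segment_id = 1, p_perm = 1))), 0)

  # planted effects in specific segments of a small hierarchy are the ones
  # selected: build a 2-level tree and plant a shift in two leaf segments
  tpl <- fix_template
  dir2 <- localized_direction(tpl, center = 30, bandwidth = 0.25)
  co <- simulate_cohort(tpl, n = 300, effect_direction = dir2, effect_size = 1.2,
                        noise_sd = 0.02, seed = 43)
  al <- prep_cohort(co$configs, tpl$pair_map)
  sh <- adjust_covariates(
    al$shapes,
    cbind(as.matrix(co$covariates[, c("sex", "age", "height", "weight")]),
          size = al$centroid_sizes))
  hier <- spectral_hierarchy(build_similarity(fix_shapes), levels = 2, seed = 1)
  models <- lapply(1:7, function(sid)
    fit_segment_model(fix_shapes, hier, sid, pa_reps = 40, seed = sid))
  traits <- fit_traits(sh, co$group, models, n_perm = 499, seed = 44)
  sel <- select_traits(traits, alpha = 0.05)
  # the planted displacement is concentrated near landmark 30 and its
  # mirror: every segment containing those landmarks must be selected
  w <- matrix(dir2, ncol = 3, byrow = TRUE)
  hot <- which(rowSums(w^2) > 0.25 * max(rowSums(w^2)))
  hit_segments <- which(vapply(1:7, function(sid)
    length(intersect(segment_landmarks(hier, sid), hot)) > 0, TRUE))
  expect_true(all(hit_segments %in% sel$segment_id))
  expect_s3_class(tidy(traits), "tbl_df")
  expect_equal(glance(traits)$n_traits, 7)
})

test_that("cosine distance behaves as an angle-based score", {
  d <- c(1, 0, 0) # trait direction
  expect_equal(cosine_score(d, 3 * d), 0)
  expect_equal(cosine_score(d, c(0, 2, 0)), 1)
  expect_equal(cosine_score(d, -d), 2)
  # scale invariance in the individual's PC vector
  v <- c(0.3, -1, 2)
  expect_equal(cosine_score(d, v), cosine_score(d, 100 * v))
  expect_error(cosine_score(d, c(0, 0, 0)), "zero")
  # matrix input gives one score per row
  expect_equal(cosine_score(d, rbind(d, -d)), c(0, 2))
})

test_that("Li-Ji effective test count responds to trait correlation", {
  set.seed(45)
  # independent traits: m_eff equals the trait count
  s5 <- matrix(rnorm(300 * 5), 300, 5)
  expect_equal(effective_tests(s5)$m_eff, 5)

  # three perfectly correlated traits: the all-ones correlation matrix has
  # eigenvalues (3, 0, 0), hand-checked, so one effective test
  base <- rnorm(100)
  expect_equal(effective_tests(cbind(base, 2 * base + 1, 3 * base))$m_eff, 1)

  # 41 independent traits: Bonferroni threshold prints as 1.2e-3
  s41 <- matrix(rnorm(250 * 41), 250, 41)
  et41 <- effective_tests(s41, alpha = 0.05)
  expect_equal(et41$m_eff, 41)
  expect_equal(signif(et41$bonferroni, 2), 1.2e-3)

  # monotone: stronger equicorrelation lowers m_eff
  equi <- function(rho) {
    z <- matrix(rnorm(400 * 8), 400, 8)
    f <- rnorm(400)
    sqrt(rho) * f + sqrt(1 - rho) * z
  }
  m_low <- effective_tests(equi(0.3))$m_eff
  m_high <- effective_tests(equi(0.9))$m_eff
  expect_lte(m_high, m_low)
  expect_gte(m_high, 1)

  expect_warning(effective_tests(cbind(s5, 1)), "constant")
  expect_error(effective_tests(s5[, 1, drop = FALSE]), "at least 2")
})

test_that("planted trait directions are recovered with growing samples", {
  tpl <- fix_template
  dirp <- localized_direction(tpl, center = 55, bandwidth = 0.3)
  hier <- spectral_hierarchy(build_similarity(fix_shapes), levels = 1, seed = 1)
  mdl <- fit_segment_model(fix_shapes, hier, 1, pa_reps = 40, seed = 46)
  angles <- vapply(c(200, 1000), function(n) {  # 100 and 500 per group
    co <- simulate_cohort(tpl, n = n, effect_direction = dirp, effect_size = 1,
                          noise_sd = 0.02, seed = 47)
    al <- prep_cohort(co$configs, tpl$pair_map)
    sh <- adjust_covariates(
      al$shapes,
      cbind(as.matrix(co$covariates[, c("sex", "age", "height", "weight")]),
            size = al$centroid_sizes))
    pc <- project_segment(mdl, sh)
    est <- plsr_contrast(pc, co$group)$direction
    # reference: the planted template deformation, restricted to the
    # segment and expressed linearly in the model basis
    w <- matrix(dirp, ncol = 3, byrow = TRUE)[mdl$landmarks, ]
    ref <- as.vector(crossprod(mdl$basis, as.vector(t(w))))
    acos(pmin(1, abs(sum(est * ref)) / sqrt(sum(ref^2)))) * 180 / pi
  }, 1)
  expect_lt(angles[2], 10)
  expect_lte(angles[2], angles[1] + 5)   # error shrinks (or stays) with n
})
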