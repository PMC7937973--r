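# 4-point hand template: two midline points, one left/right pair
hand_tpl <- list(
  coords = rbind(c(0, 1, 0), c(0, -1, 0), c(1, 0, 0.5), c(-1, 0, 0.5)),
  pair_map = c(1L, 2L, 4L, 3L))

test_that("reflection negates x, re-pairs landmarks, and is an involution", {
  cf <- hand_tpl$coords
  expect_equal(reflect_landmarks(cf, hand_tpl$pair_map), cf)  # symmetric input

  # displace the left landmark (index 4): its right partner moves in the
  # reflection, by hand: reflected row 3 = (-1) * x of old row 4 etc.
  cf2 <- cf
  cf2[4, ] <- cf2[4, ] + c(-0.2, 0.1, 0.3)
  refl <- reflect_landmarks(cf2, hand_tpl$pair_map)
  expect_equal(refl[3, ], c(1.2, 0.1, 0.8))     # partner displaced
  expect_equal(refl[4, ], c(-1, 0, 0.5))        # right landmark now pristine
  expect_equal(reflect_landmarks(refl, hand_tpl$pair_map), cf2)  # involution

  expect_error(reflect_landmarks(cf, c(1L, 2L, 3L)), "length")
  expect_error(reflect_landmarks(cf, c(2L, 3L, 4L, 1L)), "involution")
})

test_that("symmetrization averages pairs and yields a reflection fixed point", {
  # two-point toy, already in a common frame: plain arithmetic mean
  a <- rbind(c(1, 0, 0), c(-1, 0.2, 0))
  b <- rbind(c(0.5, 0.1, 0), c(-0.8, 0.1, 0))
  expect_equal(symmetrize_landmarks(a, b, align = FALSE), (a + b) / 2)
  expect_error(symmetrize_landmarks(a, b[1, , drop = FALSE]), "mismatch")

  cf <- hand_tpl$coords
  expect_equal(symmetrize_landmarks(cf, cf, align = FALSE), cf)

  # asymmetric face: symmetrized output is a fixed point of reflection
  set.seed(20)
  cf2 <- cf + matrix(rnorm(12, 0, 0.05), 4)
  sym <- symmetrize_landmarks(cf2, reflect_landmarks(cf2, hand_tpl$pair_map))
  expect_equal(reflect_landmarks(sym, hand_tpl$pair_map), sym, tolerance = 1e-8)
})

test_that("GPA removes position, orientation and scale exactly", {
  set.seed(21)
  A <- matrix(rnorm(30), 10, 3)
  R <- random_rotation(1)
  B <- 2.5 * A %*% R + matrix(rep(c(3, -1, 2), each = 10), 10, 3)
  al <- gpa(list(A, B))
  expect_lt(sqrt(mean((al$shapes[1, ] - al$shapes[2, ])^2)), 1e-8)
  # centering: every aligned configuration has its centroid at the origin
  cents <- apply(al$shapes, 1, function(v)
    sqrt(sum(colMeans(matrix(v, ncol = 3, byrow = TRUE))^2)))
  expect_true(all(cents < 1e-10))
  expect_equal(al$centroid_sizes[2] / al$centroid_sizes[1], 2.5, tolerance = 1e-8)
})

test_that("GPA consensus ignores rigid motion of inputs and decreases its objective", {
  set.seed(22)
  A <- matrix(rnorm(24), 8, 3)
  B <- matrix(rnorm(24), 8, 3)
  rotA <- A %*% random_rotation(2) + 1.5
  c1 <- gpa(list(A, rotA, B))$consensus
  c2 <- gpa(list(A, A, B))$consensus
  # consensus frames can differ by a rotation: compare after superimposition
  d <- vegan::procrustes(c1, c2, scale = FALSE, symmetric = FALSE)
  expect_lt(sqrt(mean((d$Yrot - c1)^2)), 1e-6)

  co <- simulate_cohort(fix_template, n = 15, seed = 23)
  al <- gpa(co$configs)
  expect_true(all(diff(al$rss_path) <= 1e-10))

  # whole-pipeline equivariance: pre-rotating every input changes nothing
  R <- random_rotation(3)
  rot <- co$configs
  for (i in 1:15) rot[i, , ] <- co$configs[i, , ] %*% R
  expect_equal(gpa(rot)$shapes, al$shapes, tolerance = 1e-6)

  expect_error(gpa(list(A)), "at least 2")
  expect_error(gpa(list(A * 0, A * 0)), "degenerate")
})

test_that("pairwise GPA agrees with an independent Procrustes implementation", {
  set.seed(24)
  X <- matrix(rnorm(36), 12, 3)
  Y <- 1.7 * X %*% random_rotation(4) + 0.3 + matrix(rnorm(36, 0, 0.05), 12, 3)
  al <- gpa(list(X, Y), remove_scale = FALSE)
  d_pkg <- sum((al$shapes[1, ] - al$shapes[2, ])^2)
  # vegan's best-fit residual for Y onto X (translation+rotation+scale is
  # not symmetric, so compare the symmetric Procrustes statistic ordering)
  v <- vegan::procrustes(scale(X, scale = FALSE), scale(Y, scale = FALSE),
                         scale = FALSE)
  d_veg <- sum((v$Yrot - scale(X, scale = FALSE))^2)
  # joint-consensus alignment cannot beat direct pairwise superimposition
  # by more than numerical slack, nor be dramatically worse
  expect_gt(d_pkg, 0.5 * d_veg)
  expect_lt(d_pkg, 2.0 * d_veg)
})

test_that("QC flags a planted gross outlier and is threshold-monotone", {
  co <- simulate_cohort(fix_template, n = 40, seed = 25)
  cfg <- co$configs
  cfg[7, , ] <- cfg[7, , ] + matrix(rnorm(fix_template$p * 3, 0, 0.4),
                                    fix_template$p, 3)
  al <- gpa(cfg)
  qc <- qc_scores(al, z_threshold = 2)
  expect_true(qc$flag[7])
  # oracle: direct Mahalanobis in the same reduced basis
  k <- sum(cumsum(prcomp(al$shapes)$sdev^2) / sum(prcomp(al$shapes)$sdev^2) < 0.98) + 1
  pc <- prcomp(al$shapes)
  d_direct <- sqrt(stats::mahalanobis(pc$x[, 1:k], rep(0, k),
                                      diag(pc$sdev[1:k]^2)))
  expect_equal(qc$mahalanobis, unname(d_direct), tolerance = 1e-8)
  # monotone: raising the threshold never adds flags
  qc4 <- qc_scores(al, z_threshold = 4)
  expect_true(all(qc$flag | !qc4$flag))
  # an individual placed exactly at the mean scores distance ~ 0
  cfg2 <- al$shapes
  cfg2[1, ] <- colMeans(cfg2[-1, ])
  # not exactly the mean of all rows, so just check it is the minimum
  qc2 <- qc_scores(rbind(colMeans(cfg2), cfg2), z_threshold = 2)
  expect_equal(which.min(qc2$mahalanobis), 1L)
})

test_that("PLSR covariate adjustment equals least-squares residualization", {
  set.seed(26)
  n <- 50
  covs <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n), h = rnorm(n))
  L <- matrix(rnorm(3 * 12), 3, 12)
  noise <- matrix(rnorm(n * 12, 0, 0.05), n, 12)
  shapes <- 5 + scale(covs, scale = FALSE) %*% L + noise

  res <- adjust_covariates(shapes, covs)
  # residual columns are uncorrelated with every covariate
  expect_lt(max(abs(cor(res, covs))), 1e-8)
  # oracle: OLS residuals (plus grand mean) from lm()
  fit <- lm(shapes ~ covs)
  expect_equal(unclass(res),
               fit$residuals + matrix(colMeans(shapes), n, 12, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
  # recovered covariate effect within 2% (Frobenius) of the planted one
  eff <- attr(res, "fitted_effect")
  truth <- scale(covs, scale = FALSE) %*% L
  expect_lt(norm(eff - truth, "F") / norm(truth, "F"), 0.02)

  # a covariate exactly orthogonal to the shapes leaves them untouched
  v <- rep(c(1, -1), length.out = n)
  sh_orth <- shapes - outer(v, colSums(v * shapes) / sum(v * v))
  expect_equal(unclass(adjust_covariates(sh_orth, cbind(v))), sh_orth,
               tolerance = 1e-8, ignore_attr = TRUE)

  # perfect linear dependence: residuals collapse to the column means
  exact <- scale(covs, scale = FALSE) %*% L + 2
  rese <- adjust_covariates(exact, covs)
  expect_equal(unclass(rese), matrix(colMeans(exact), n, 12, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)

  # rank-deficient covariates: capped with a warning
  expect_warning(adjust_covariates(shapes, cbind(covs, covs[, 1])), "rank")
})
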