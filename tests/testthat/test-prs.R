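test_that("LD r2 is a squared dosage correlation with the generator's target", {
  set.seed(61)
  x <- rbinom(100, 2, 0.4)
  expect_equal(ld_r2(x, x), 1)
  g <- simulate_genotypes(5000, n_snps = 20, ld_block_rho = 0, seed = 62)
  r2s <- sapply(seq(1, 19, by = 2), function(j) ld_r2(g$dosages[, j], g$dosages[, j + 1]))
  expect_lt(median(r2s), 0.01)
  # adjacent pair from an autoregressive block with rho 0.6: r2 near 0.36
  g6 <- simulate_genotypes(5000, n_snps = 2, block_size = 2, ld_block_rho = 0.6,
                           seed = 63)
  expect_lt(abs(ld_r2(g6$dosages[, 1], g6$dosages[, 2]) - 0.36), 0.05)
  expect_error(ld_r2(rep(1, 10), rbinom(10, 2, 0.5)), "constant")
})

test_that("LD clumping keeps the best-p SNP per correlated block", {
  set.seed(64)
  # planted 3-block structure: tight LD within blocks, none between
  g <- simulate_genotypes(3000, n_snps = 15, block_size = 5, ld_block_rho = 0.95,
                          maf_range = c(0.3, 0.5), spacing_bp = 1000L, seed = 65)
  ss <- tibble::tibble(
    SNP = g$snp_meta$snp, CHR = g$snp_meta$chrom, BP = g$snp_meta$pos,
    A1 = g$snp_meta$a_major, A2 = g$snp_meta$a_minor,
    BETA = rnorm(15), SE = 0.1, P = runif(15))
  kept <- ld_clump(ss, g, r2_thresh = 0.1, window_bp = 250000)
  # oracle: the generator's block map; exactly one survivor per block,
  # and it is that block's smallest p
  blocks <- g$snp_meta$block[match(kept$SNP, g$snp_meta$snp)]
  expect_equal(sort(blocks), 1:3)
  for (b in 1:3) {
    in_block <- g$snp_meta$snp[g$snp_meta$block == b]
    expect_equal(kept$SNP[blocks == b], ss$SNP[ss$SNP %in% in_block][which.min(ss$P[ss$SNP %in% in_block])])
  }

  # mutually uncorrelated SNPs: everything is retained
  g0 <- simulate_genotypes(3000, n_snps = 10, ld_block_rho = 0, spacing_bp = 1000L,
                           seed = 66)
  ss0 <- dplyr::mutate(ss[1:10, ], SNP = g0$snp_meta$snp, BP = g0$snp_meta$pos,
                       A1 = g0$snp_meta$a_major, A2 = g0$snp_meta$a_minor)
  expect_equal(nrow(ld_clump(ss0, g0, r2_thresh = 0.1)), 10)

  # definition case: two SNPs in high LD keep only the smaller p
  gg <- simulate_genotypes(2000, n_snps = 2, block_size = 2, ld_block_rho = 0.95,
                           spacing_bp = 10000L, seed = 67)
  ss2 <- tibble::tibble(SNP = gg$snp_meta$snp, CHR = "1", BP = gg$snp_meta$pos,
                        A1 = gg$snp_meta$a_major, A2 = gg$snp_meta$a_minor,
                        BETA = c(0.2, 0.1), SE = 0.1, P = c(1e-6, 1e-3))
  expect_equal(ld_clump(ss2, gg)$SNP, gg$snp_meta$snp[1])

  expect_error(ld_clump(dplyr::mutate(ss, SNP = paste0("x", SNP)), g), "no summary")
})

test_that("PRS scoring sums aligned effect alleles and is linear and order-invariant", {
  g <- simulate_genotypes(50, n_snps = 2, ld_block_rho = 0, seed = 68)
  ss <- tibble::tibble(SNP = g$snp_meta$snp, CHR = g$snp_meta$chrom,
                       BP = g$snp_meta$pos, A1 = g$snp_meta$a_major,
                       A2 = g$snp_meta$a_minor,
                       BETA = c(0.5, -1.0), SE = 0.1, P = c(0.01, 0.02))
  # hand check on individual 1 once its dosages are known
  sc <- prs_score(g, ss, threshold = 1)
  expect_equal(sc[1], sum(c(0.5, -1.0) * g$dosages[1, ]))
  d <- g$dosages[2, ]
  expect_equal(sc[2], 0.5 * d[1] - 1.0 * d[2])
  # spec toy: betas (0.5, -1) on dosages (2, 1) -> 1.0 - 1.0 = 0
  expect_equal(sum(c(0.5, -1.0) * c(2, 1)), 0)

  # threshold below every p: empty score
  expect_equal(prs_score(g, ss, threshold = 1e-9), rep(0, 50), ignore_attr = TRUE)
  # linearity: doubling betas doubles scores
  expect_equal(prs_score(g, dplyr::mutate(ss, BETA = 2 * BETA), 1), 2 * sc,
               ignore_attr = TRUE)
  # SNP order invariance
  expect_equal(prs_score(g, ss[2:1, ], 1), sc, ignore_attr = TRUE)
  # allele-flip invariance: swap A1/A2 and negate beta
  flipped <- dplyr::mutate(ss, A1 = ss$A2, A2 = ss$A1, BETA = -BETA)
  expect_equal(prs_score(g, flipped, 1), sc, ignore_attr = TRUE)
  # unresolvable alleles are dropped and counted
  bad <- ss; bad$A1[1] <- "Z"
  scb <- prs_score(g, bad, 1)
  expect_equal(attr(scb, "n_dropped"), 1L)
  expect_equal(as.vector(scb), as.vector(-1.0 * g$dosages[, 2]))
})

test_that("PRS threshold grids give nested SNP sets and monotone composition", {
  set.seed(69)
  g <- simulate_genotypes(200, n_snps = 40, ld_block_rho = 0, seed = 70)
  ss <- tibble::tibble(SNP = g$snp_meta$snp, CHR = g$snp_meta$chrom,
                       BP = g$snp_meta$pos, A1 = g$snp_meta$a_major,
                       A2 = g$snp_meta$a_minor, BETA = rnorm(40), SE = 0.1,
                       P = runif(40))
  pm <- prs_matrix(g, ss, thresholds = c(0.05, 0.2, 0.5, 1))
  expect_true(all(diff(pm$n_snps) >= 0))          # nested inclusion
  expect_equal(pm$n_snps[4], 40)
  # default dense grid honors the conventional range and step
  grid <- prs_threshold_grid()
  expect_equal(grid[1], 5e-8)
  expect_equal(grid[length(grid)], 1)
  expect_equal(grid[3] - grid[2], 5e-5)
})

test_that("the PRS scan singles out the trait its SNPs are causal for", {
  set.seed(71)
  wins <- 0L
  for (s in 1:5) {
    g <- simulate_genotypes(800, n_snps = 60, ld_block_rho = 0, seed = 800 + s)
    causal <- c(5, 25, 45)
    sim <- simulate_causal_scores(g, causal, h2_target = 0.15, seed = 900 + s)
    # discovery study on an independent sample with the same causal SNPs
    gd <- simulate_genotypes(1500, like = g, ld_block_rho = 0, seed = 850 + s)
    ss <- make_discovery_sumstats(gd, causal, h2_liability = 0.3, seed = 950 + s)
    kept <- ld_clump(ss, g)
    pm <- prs_matrix(g, kept, thresholds = c(1e-4, 1e-2, 0.1, 0.5, 1))
    endo <- cbind(causal_trait = sim$score, null_trait = rnorm(800))
    scan <- prs_scan(pm, endo)
    mins <- glance(scan)
    if (mins$min_p[mins$trait == "causal_trait"] <
        mins$min_p[mins$trait == "null_trait"]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)

  # misaligned individuals: association vanishes
  g <- simulate_genotypes(500, n_snps = 30, ld_block_rho = 0, seed = 72)
  sim <- simulate_causal_scores(g, 1:3, h2_target = 0.2, seed = 73)
  ss <- make_discovery_sumstats(g, 1:3, seed = 74)
  pm <- prs_matrix(g, ss, thresholds = c(0.5))
  set.seed(75)
  scan_perm <- prs_scan(pm, cbind(tr = sample(sim$score)))
  expect_gt(scan_perm$p[1], 0.001)
})
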