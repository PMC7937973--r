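#' Simulate biallelic genotype dosages with block LD
#'
#' Draws hard-call dosages under Hardy-Weinberg equilibrium with a
#' first-order autoregressive LD structure inside blocks: within a block
#' every SNP shares one minor allele frequency, and each haplotype allele is
#' copied from the previous SNP with probability `ld_block_rho` or redrawn
#' as a fresh Bernoulli(maf). Adjacent genotypes then correlate at exactly
#' `ld_block_rho` in expectation and SNPs `k` apart at `rho^k`. SNPs on the
#' X chromosome are hemizygous in males and coded 0/2 so they match the
#' 0/1/2 female coding.
#'
#' @param n Number of individuals.
#' @param n_snps Number of SNPs.
#' @param block_size SNPs per LD block (last block may be shorter).
#' @param ld_block_rho Within-block adjacent-haplotype copy probability,
#'   in `[0, 1)`.
#' @param maf_range Interval within (0, 0.5] the per-block MAF is drawn from.
#' @param chrom Chromosome labels; recycled across blocks. Use `"X"` to get
#'   hemizygous male coding.
#' @param sex Optional 0/1 vector (1 = male) of length `n`; required when any
#'   chromosome is `"X"`.
#' @param spacing_bp Base-pair spacing between consecutive SNPs on a
#'   chromosome.
#' @param like Optional `endo_geno` whose SNP panel (ids, positions,
#'   alleles, per-block MAFs, blocks) is reused, so the new draw represents
#'   fresh individuals genotyped on the same variants (e.g. an independent
#'   discovery cohort). Overrides `n_snps`, `block_size`, `maf_range` and
#'   `chrom`.
#' @param seed Integer seed.
#'
#' @return An `endo_geno` list: `dosages` (n x n_snps, major-allele counts in
#'   0..2), `snp_meta` (tibble: snp, chrom, pos, a_major, a_minor, maf,
#'   block), `sex`.
#' @export
simulate_genotypes <- function(n, n_snps,
                               block_size = 10,
                               ld_block_rho = 0,
                               maf_range = c(0.05, 0.5),
                               chrom = "1",
                               sex = NULL,
                               spacing_bp = 10000L,
                               like = NULL,
                               seed = 1) {
  n <- check_count(n, 2L, "n")
  if (is.null(like)) {
    n_snps <- check_count(n_snps, 1L, "n_snps")
    if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
      abort("`maf_range` must lie within (0, 0.5]")
  }
  if (ld_block_rho < 0 || ld_block_rho >= 1)
    abort("`ld_block_rho` must be in [0, 1)")
  set.seed(seed)

  if (!is.null(like)) {
    stopifnot(inherits(like, "endo_geno"))
    meta <- like$snp_meta
    n_snps <- nrow(meta)
    block <- meta$block
    n_blocks <- max(block)
    chrom_of_block <- meta$chrom[match(seq_len(n_blocks), block)]
    maf_block <- meta$maf[match(seq_len(n_blocks), block)]
  } else {
    n_blocks <- ceiling(n_snps / block_size)
    block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_snps)]
    chrom_of_block <- rep_len(as.character(chrom), n_blocks)
    maf_block <- stats::runif(n_blocks, maf_range[1], maf_range[2])
  }
  chrom_snp <- chrom_of_block[block]
  if (any(chrom_snp == "X") && is.null(sex))
    abort("`sex` (0/1, 1 = male) is required when X-chromosome SNPs are simulated")
  if (is.null(sex)) sex <- rep(0L, n)
  stopifnot(length(sex) == n)
  maf_snp <- maf_block[block]

  # haplotype-copy chain per block: allele j+1 equals allele j w.p. rho
  draw_hap <- function(m, maf, k) {
    h <- matrix(0L, m, k)
    h[, 1] <- stats::rbinom(m, 1, maf)
    if (k > 1) for (j in 2:k) {
      copy <- stats::rbinom(m, 1, ld_block_rho)
      h[, j] <- ifelse(copy == 1L, h[, j - 1], stats::rbinom(m, 1, maf))
    }
    h
  }

  dosages <- matrix(0L, n, n_snps)
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    k <- length(idx)
    if (chrom_of_block[b] == "X") {
      h1 <- draw_hap(n, maf_block[b], k)
      h2 <- draw_hap(n, maf_block[b], k)
      g <- h1 + h2
      male <- sex == 1L
      g[male, ] <- 2L * h1[male, , drop = FALSE]   # hemizygous: 0/2
      dosages[, idx] <- g
    } else {
      dosages[, idx] <- draw_hap(n, maf_block[b], k) + draw_hap(n, maf_block[b], k)
    }
  }
  # minor-allele counts -> major-allele additive coding
  dosages <- 2L - dosages

  if (!is.null(like)) {
    snp_meta <- like$snp_meta
  } else {
    pos <- stats::ave(seq_len(n_snps), chrom_snp,
                      FUN = function(i) seq_along(i) * spacing_bp)
    alleles <- c("A", "C", "G", "T")
    a1 <- sample(alleles, n_snps, replace = TRUE)
    a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1), "")
    snp_meta <- tibble(
      snp = sprintf("rs%06d", seq_len(n_snps)),
      chrom = chrom_snp, pos = as.integer(pos),
      a_major = a1, a_minor = a2, maf = maf_snp, block = block)
  }

  structure(list(
    dosages = dosages,
    snp_meta = snp_meta,
    sex = as.integer(sex)
  ), class = "endo_geno")
}

#' @export
print.endo_geno <- function(x, ...) {
  cat(sprintf("<endo_geno> %d individuals x %d SNPs (%d blocks, chrom: %s)\n",
              nrow(x$dosages), ncol(x$dosages), max(x$snp_meta$block),
              paste(unique(x$snp_meta$chrom), collapse = ",")))
  invisible(x)
}

#' Simulate a quantitative score with chosen causal SNPs and heritability
#'
#' Builds `score = sum_j beta_j * (dosage_j - mean_j) + e`, with the betas
#' scaled so the causal SNPs explain `h2_target` of the score variance in
#' expectation.
#'
#' @param genotypes An [simulate_genotypes()] object.
#' @param causal_idx Indices of causal SNPs.
#' @param h2_target Fraction of score variance explained by the causal set,
#'   in `[0, 1)`.
#' @param betas Relative per-SNP effects (recycled); rescaled to meet
#'   `h2_target`.
#' @param seed Integer seed for the environmental residual.
#' @return A list: `score` (length n), `beta` (realized per-SNP effects on
#'   the causal set), `causal_idx`, `h2_target`.
#' @export
simulate_causal_scores <- function(genotypes, causal_idx, h2_target,
                                   betas = 1, seed = 1) {
  stopifnot(inherits(genotypes, "endo_geno"))
  if (h2_target < 0 || h2_target >= 1) abort("`h2_target` must be in [0, 1)")
  set.seed(seed)
  G <- scale(genotypes$dosages[, causal_idx, drop = FALSE], scale = FALSE)
  b <- rep_len(betas, length(causal_idx))
  genetic <- as.vector(G %*% b)
  vg <- stats::var(genetic)
  if (h2_target == 0 || vg == 0) {
    b <- b * 0
    genetic <- genetic * 0
    ve <- 1
  } else {
    ve <- vg * (1 - h2_target) / h2_target
  }
  score <- genetic + stats::rnorm(nrow(G), 0, sqrt(ve))
  list(score = score, beta = b, causal_idx = causal_idx, h2_target = h2_target)
}

#' Simulate discovery summary statistics for polygenic scoring
#'
#' Emulates an external case/control discovery study: a liability is built
#' from designated causal SNPs, individuals above the prevalence quantile
#' are cases, and each SNP is tested by score (linear) regression of the
#' case indicator on dosage. Output columns follow the usual GWAS
#' summary-statistic dialect, with `A1` the effect (major) allele.
#'
#' @param genotypes An [simulate_genotypes()] object for the discovery
#'   sample.
#' @param causal_idx Indices of liability-increasing SNPs (may be empty for
#'   a null study).
#' @param h2_liability Liability variance explained by the causal set.
#' @param prevalence Case fraction.
#' @param seed Integer seed.
#' @return A tibble with columns SNP, CHR, BP, A1, A2, BETA, SE, P.
#' @export
make_discovery_sumstats <- function(genotypes, causal_idx = integer(),
                                    h2_liability = 0.2, prevalence = 0.3,
                                    seed = 1) {
  stopifnot(inherits(genotypes, "endo_geno"))
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0,1)")
  liab <- simulate_causal_scores(genotypes, causal_idx,
                                 h2 = if (length(causal_idx)) h2_liability else 0,
                                 seed = seed)$score
  y <- as.integer(liab >= stats::quantile(liab, 1 - prevalence))
  if (length(unique(y)) < 2L) abort("degenerate phenotype: all one class")
  fit <- fast_ols_scan(y, genotypes$dosages)
  tibble(SNP = genotypes$snp_meta$snp,
         CHR = genotypes$snp_meta$chrom,
         BP = genotypes$snp_meta$pos,
         A1 = genotypes$snp_meta$a_major,
         A2 = genotypes$snp_meta$a_minor,
         BETA = fit$beta, SE = fit$se, P = fit$p)
}
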