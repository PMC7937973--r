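# vectorized simple OLS of y on each column of G (with intercept):
# beta, se, t (n-2 df), two-sided p. Constant columns give NA.
fast_ols_scan <- function(y, G) {
  G <- as.matrix(G)
  n <- length(y)
  gc <- scale(G, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  ok <- sxx > .Machine$double.eps * n
  sxy <- as.vector(crossprod(gc, yc))
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  ss_res <- sum(yc^2) - ifelse(ok, beta^2 * sxx, 0)
  sigma2 <- pmax(ss_res, 0) / (n - 2)
  se <- ifelse(ok, sqrt(sigma2 / sxx), NA_real_)
  t_ <- beta / se
  list(beta = beta, se = se, t = t_,
       p = 2 * stats::pt(abs(t_), df = n - 2, lower.tail = FALSE),
       n = n, monomorphic = !ok)
}

#' Additive major-allele genotype coding
#'
#' Codes a biallelic genotype as the count of the major allele. Autosomes
#' and female X genotypes take values 0/1/2; hemizygous male X genotypes
#' carry a single allele and are coded 0 (minor) or 2 (major) so their
#' scale matches the female coding.
#'
#' @param alleles Character vector of observed alleles for one individual
#'   at one site (length 2, or length 1 for a hemizygous male X call).
#' @param major The designated major allele.
#' @param chrom Chromosome label; `"X"` triggers hemizygous handling.
#' @param male Logical; is this individual male?
#' @return Integer dosage in `{0, 1, 2}`.
#' @export
code_genotype <- function(alleles, major, chrom = "1", male = FALSE) {
  if (length(unique(c(alleles, major))) > 2L) abort("multi-allelic site")
  if (identical(chrom, "X") && isTRUE(male)) {
    a <- alleles[1]
    return(if (a == major) 2L else 0L)
  }
  if (length(alleles) != 2L) abort("expected a diploid call")
  as.integer(sum(alleles == major))
}

#' Single-SNP association of a quantitative score
#'
#' Ordinary least squares of the endophenotype score on the SNP dosage
#' (with intercept); the t statistic `beta / se` on `n - 2` degrees of
#' freedom gives the two-sided p-value.
#'
#' @param score Numeric phenotype vector.
#' @param dosage Numeric dosage vector (same individuals).
#' @return A tibble row: beta, se, t, p, n; `NULL` (with a warning) for a
#'   monomorphic SNP.
#' @export
snp_regression <- function(score, dosage) {
  if (length(score) != length(dosage)) abort("length mismatch")
  if (length(score) < 3L) abort("need at least 3 individuals")
  f <- fast_ols_scan(score, matrix(dosage, ncol = 1))
  if (f$monomorphic[1]) {
    warn("monomorphic SNP skipped")
    return(NULL)
  }
  tibble(beta = f$beta[1], se = f$se[1], t = f$t[1], p = f$p[1], n = f$n)
}

#' Genome-wide scan of one score in one cohort
#'
#' @param score Phenotype vector.
#' @param genotypes An `endo_geno` object (see [simulate_genotypes()]).
#' @return Tibble: snp, chrom, pos, beta, se, t, p, n (monomorphic SNPs
#'   have NA statistics).
#' @export
gwas_scan <- function(score, genotypes) {
  stopifnot(inherits(genotypes, "endo_geno"))
  f <- fast_ols_scan(score, genotypes$dosages)
  dplyr::bind_cols(
    dplyr::select(genotypes$snp_meta, "snp", "chrom", "pos"),
    tibble(beta = f$beta, se = f$se, t = f$t, p = f$p, n = f$n))
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Combines per-cohort estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1 / sqrt(sum(w))`, `z = beta / se`,
#' two-sided normal p-value. A single study is returned unchanged except
#' that z replaces t.
#'
#' @param beta,se Numeric vectors of per-study estimates and standard
#'   errors (all `se > 0`).
#' @return Tibble row: beta, se, z, p, n_studies.
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) == 0L) abort("no studies to combine")
  if (length(beta) != length(se) || any(!is.finite(se)) || any(se <= 0))
    abort("each study needs a finite positive se")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  tibble(beta = b, se = s, z = z,
         p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         n_studies = length(beta))
}

#' Meta-analyze per-cohort scans across traits
#'
#' Row-binds per-cohort [gwas_scan()] tables (tagged with `trait` and
#' `cohort`) and IVW-combines every (snp, trait) cell. Cohort order does
#' not affect the result.
#'
#' @param scans A tibble with columns snp, chrom, pos, trait, cohort,
#'   beta, se.
#' @return Tibble: snp, chrom, pos, trait, beta, se, z, p, n_studies.
#' @export
meta_scans <- function(scans) {
  scans %>%
    dplyr::filter(is.finite(.data$se) & .data$se > 0) %>%
    dplyr::group_by(.data$snp, .data$chrom, .data$pos, .data$trait) %>%
    dplyr::reframe(ivw_meta(.data$beta, .data$se)) %>%
    dplyr::ungroup()
}

#' Distance-based clumping of significant SNPs into loci
#'
#' Reduces an association table to independent loci: per SNP the best
#' p-value across traits is taken; then greedily, the unassigned SNP with
#' the smallest p below `p_threshold` becomes a lead, and every unassigned
#' SNP on its chromosome within `window_bp` (inclusive both ends) joins
#' its locus. Ties on p break by (chrom, pos). Loci are disjoint and every
#' significant SNP belongs to exactly one.
#'
#' @param assoc Tibble with snp, chrom, pos, trait, p (one row per SNP x
#'   trait, e.g. from [meta_scans()]).
#' @param p_threshold Lead significance threshold (default genome-wide
#'   5e-8).
#' @param window_bp Half-window around the lead (default 500000, i.e. a
#'   1 Mb locus).
#' @return Tibble of loci: locus, lead_snp, chrom, pos, best_trait,
#'   best_p, n_member_snps, and list-column member_snps.
#' @export
clump_loci <- function(assoc, p_threshold = 5e-8, window_bp = 500000) {
  best <- assoc %>%
    dplyr::filter(is.finite(.data$p)) %>%
    dplyr::group_by(.data$snp, .data$chrom, .data$pos) %>%
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$p, .data$chrom, .data$pos)
  sig <- dplyr::filter(best, .data$p < p_threshold)
  loci <- list()
  assigned <- character(0)
  while (nrow(sig) > 0) {
    lead <- sig[1, ]
    members <- best %>%
      dplyr::filter(.data$chrom == lead$chrom,
                    abs(.data$pos - lead$pos) <= window_bp,
                    !(.data$snp %in% assigned))
    assigned <- c(assigned, members$snp)
    loci[[length(loci) + 1]] <- tibble(
      locus = length(loci) + 1L, lead_snp = lead$snp,
      chrom = lead$chrom, pos = lead$pos,
      best_trait = lead$trait, best_p = lead$p,
      n_member_snps = nrow(members), member_snps = list(members$snp))
    sig <- dplyr::filter(sig, !(.data$snp %in% assigned))
  }
  dplyr::bind_rows(loci)
}

#' Genome-wide and study-wide significance thresholds
#'
#' The genome-wide threshold is the conventional `alpha_gw`; the
#' study-wide threshold divides it by the number of traits tested
#' (Bonferroni across traits).
#'
#' @param n_traits Number of traits tested.
#' @param alpha_gw Genome-wide level (default 5e-8).
#' @return A list: `genomewide`, `studywide`.
#' @examples
#' gwas_thresholds(59)$studywide  # 8.47e-10
#' @export
gwas_thresholds <- function(n_traits, alpha_gw = 5e-8) {
  n_traits <- check_count(n_traits, 1L, "n_traits")
  list(genomewide = alpha_gw, studywide = alpha_gw / n_traits)
}

#' Annotate loci by proximity to reference lead positions
#'
#' Marks each locus whose lead SNP lies within `window_bp` of any reference
#' position on the same chromosome (e.g. lead SNPs from a prior GWAS of the
#' same phenotype family) and reports the overlap percentage.
#'
#' @param loci A [clump_loci()] table.
#' @param reference Tibble with columns chrom, pos of reference lead SNPs.
#' @param window_bp Proximity window (default 500000).
#' @return A list: `loci` (input plus logical `near_reference`),
#'   `n_overlap`, `percent_overlap` (0-100).
#' @export
annotate_overlap <- function(loci, reference, window_bp = 500000) {
  near <- vapply(seq_len(nrow(loci)), function(i) {
    any(reference$chrom == loci$chrom[i] &
          abs(reference$pos - loci$pos[i]) <= window_bp)
  }, TRUE)
  list(loci = dplyr::mutate(loci, near_reference = near),
       n_overlap = sum(near),
       percent_overlap = round(100 * sum(near) / max(1L, nrow(loci))))
}
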