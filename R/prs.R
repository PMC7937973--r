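#' LD between two SNPs as squared Pearson correlation of dosages
#'
#' @param dosage_i,dosage_j Dosage vectors over the same individuals.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_i, dosage_j) {
  if (length(dosage_i) != length(dosage_j)) abort("length mismatch")
  if (stats::sd(dosage_i) == 0 || stats::sd(dosage_j) == 0)
    abort("constant dosage vector")
  stats::cor(dosage_i, dosage_j)^2
}

#' LD-based clumping of discovery summary statistics
#'
#' Intersects the summary statistics with the target genotypes (mismatched
#' SNPs are dropped), then greedily by ascending p: the best remaining SNP
#' is retained as an index SNP and every other remaining SNP on its
#' chromosome within `window_bp` whose dosage r-squared with it exceeds
#' `r2_thresh` is removed. Ties on p break by (chrom, pos). The target
#' cohort's own genotypes serve as the LD reference.
#'
#' @param sumstats Tibble with columns SNP, CHR, BP, A1, A2, BETA, SE, P.
#' @param genotypes An `endo_geno` LD reference / target.
#' @param r2_thresh LD pruning threshold (default 0.1).
#' @param window_bp Half-window in bp (default 250000).
#' @return The retained subset of `sumstats`, p-ascending.
#' @export
ld_clump <- function(sumstats, genotypes, r2_thresh = 0.1, window_bp = 250000) {
  stopifnot(inherits(genotypes, "endo_geno"))
  idx <- match(sumstats$SNP, genotypes$snp_meta$snp)
  keep <- !is.na(idx)
  if (!any(keep)) abort("no summary-stat SNPs found in the genotype reference")
  ss <- sumstats[keep, ]
  col <- idx[keep]
  ord <- order(ss$P, ss$CHR, ss$BP)
  ss <- ss[ord, ]; col <- col[ord]
  alive <- rep(TRUE, nrow(ss))
  retained <- logical(nrow(ss))
  sds <- apply(genotypes$dosages[, col, drop = FALSE], 2, stats::sd)
  for (i in seq_len(nrow(ss))) {
    if (!alive[i]) next
    retained[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & ss$CHR == ss$CHR[i] & abs(ss$BP - ss$BP[i]) <= window_bp)
    if (length(cand)) {
      r2 <- rep(0, length(cand))
      valid <- sds[cand] > 0 & sds[i] > 0
      if (any(valid)) {
        r2[valid] <- stats::cor(genotypes$dosages[, col[i]],
                                genotypes$dosages[, col[cand[valid]], drop = FALSE])^2
      }
      alive[cand[r2 > r2_thresh]] <- FALSE
    }
  }
  ss[retained, ]
}

#' Polygenic risk score at one inclusion threshold
#'
#' `score_i = sum over SNPs with p <= threshold of beta * dosage_i`, after
#' aligning each summary-stat effect allele with the dosage coding: when
#' the dosage counts the summary's other allele the beta sign is flipped;
#' SNPs whose alleles cannot be reconciled are dropped (and counted).
#' Missing dosages are imputed at twice the effect-allele frequency.
#'
#' @param genotypes An `endo_geno` target cohort.
#' @param sumstats (Clumped) summary statistics.
#' @param threshold Inclusion p-value threshold.
#' @return Numeric per-individual score vector; attributes `n_snps` (SNPs
#'   included) and `n_dropped` (allele mismatches).
#' @export
prs_score <- function(genotypes, sumstats, threshold = 1) {
  stopifnot(inherits(genotypes, "endo_geno"))
  ss <- sumstats[sumstats$P <= threshold, , drop = FALSE]
  n <- nrow(genotypes$dosages)
  if (nrow(ss) == 0)
    return(structure(rep(0, n), n_snps = 0L, n_dropped = 0L))
  idx <- match(ss$SNP, genotypes$snp_meta$snp)
  meta <- genotypes$snp_meta[idx, ]
  same <- ss$A1 == meta$a_major & ss$A2 == meta$a_minor
  flip <- ss$A1 == meta$a_minor & ss$A2 == meta$a_major
  usable <- !is.na(idx) & (same | flip)
  n_dropped <- sum(!usable)
  ss <- ss[usable, ]; idx <- idx[usable]
  beta <- ifelse(same[usable], ss$BETA, -ss$BETA)  # align to major-allele dosage
  G <- genotypes$dosages[, idx, drop = FALSE]
  if (anyNA(G)) {
    fill <- 2 * (1 - genotypes$snp_meta$maf[idx])   # dosage counts major allele
    for (j in seq_along(idx)) G[is.na(G[, j]), j] <- fill[j]
  }
  structure(as.vector(G %*% beta),
            n_snps = nrow(ss), n_dropped = n_dropped)
}

#' Polygenic risk scores across an inclusion-threshold grid
#'
#' @inheritParams prs_score
#' @param thresholds Increasing vector of inclusion p-value thresholds
#'   (default the conventional dense scan from 5e-8 to 1; SNP sets are
#'   nested across the grid).
#' @return An `endo_prs` list: `scores` (individuals x thresholds),
#'   `thresholds`, `n_snps` per threshold.
#' @export
prs_matrix <- function(genotypes, sumstats,
                       thresholds = prs_threshold_grid()) {
  thresholds <- sort(unique(thresholds))
  if (any(thresholds <= 0 | thresholds > 1)) abort("thresholds must be in (0, 1]")
  cols <- lapply(thresholds, function(th) prs_score(genotypes, sumstats, th))
  structure(list(
    scores = do.call(cbind, lapply(cols, as.vector)),
    thresholds = thresholds,
    n_snps = vapply(cols, attr, 1L, "n_snps")),
    class = "endo_prs")
}

#' Conventional PRS inclusion-threshold grid
#'
#' The dense scan runs from genome-wide significance (5e-8) to 1 in steps
#' of `step`; coarser grids are useful at desk scale.
#'
#' @param from,to,step Grid range and increment.
#' @return Increasing numeric vector (always includes `from` and `to`).
#' @export
prs_threshold_grid <- function(from = 5e-8, to = 1, step = 5e-5) {
  unique(c(from, seq(step, to, by = step), to))
}

#' @export
print.endo_prs <- function(x, ...) {
  cat(sprintf("<endo_prs> %d individuals x %d thresholds (%d-%d SNPs)\n",
              nrow(x$scores), length(x$thresholds),
              min(x$n_snps), max(x$n_snps)))
  invisible(x)
}

#' Scan PRS-endophenotype associations across thresholds
#'
#' For every (trait, threshold) pair fits the linear regression of the
#' polygenic risk score (response) on the endophenotype score (predictor)
#' and records beta, se, t and p; thresholds at which no SNP enters (a
#' constant PRS column) are skipped. The per-trait minimum p across
#' thresholds is the quantity usually plotted and tested against
#' `alpha / m_eff`.
#'
#' @param prs An [prs_matrix()] object.
#' @param endo_scores n x t matrix of per-individual endophenotype scores
#'   (columns named by trait).
#' @return An `endo_prs_scan` tibble: trait, threshold, n_snps, beta, se,
#'   t, p.
#' @export
prs_scan <- function(prs, endo_scores) {
  stopifnot(inherits(prs, "endo_prs"))
  endo_scores <- as.matrix(endo_scores)
  if (nrow(endo_scores) != nrow(prs$scores)) abort("individuals not aligned")
  traits <- colnames(endo_scores)
  if (is.null(traits)) traits <- sprintf("trait%d", seq_len(ncol(endo_scores)))
  rows <- list()
  for (j in seq_along(prs$thresholds)) {
    y <- prs$scores[, j]
    if (stats::sd(y) == 0) next
    f <- fast_ols_scan(y, endo_scores)
    rows[[length(rows) + 1]] <- tibble(
      trait = traits, threshold = prs$thresholds[j],
      n_snps = prs$n_snps[j],
      beta = f$beta, se = f$se, t = f$t, p = f$p)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("endo_prs_scan", class(out))
  out
}

#' @rdname prs_scan
#' @param x An `endo_prs_scan`.
#' @param ... Ignored.
#' @export
glance.endo_prs_scan <- function(x, ...) {
  x %>%
    dplyr::group_by(.data$trait) %>%
    dplyr::summarise(min_p = min(.data$p),
                     best_threshold = .data$threshold[which.min(.data$p)],
                     .groups = "drop")
}
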