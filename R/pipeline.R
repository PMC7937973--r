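#' Default end-to-end pipeline configuration
#'
#' Returns the full parameter list consumed by [run_pipeline()], with every
#' stage parameter at its conventional value (five segmentation levels,
#' 10,000 permutations, alpha 0.05, genome-wide 5e-8, ±500 kb locus
#' clumping, LD r2 0.1 / ±250 kb PRS clumping). Desk-scale analyses
#' typically shrink `n_*`, `n_perm` and the PRS grid.
#'
#' @param ... Named overrides of any default.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    p = 250, seed = 1,
    # cohorts
    n_euro = 400, n_parent_group = 150, n_unselected = 150,
    effect_center = 10L, effect_size = 1, noise_sd = 0.02,
    # segmentation
    levels = 5, pa_reps = 100, pa_percentile = 0.95,
    # traits
    n_perm = 10000, alpha = 0.05,
    # genotypes / gwas
    n_snps = 200, block_size = 10, ld_block_rho = 0.5,
    causal_idx = c(15L, 45L), h2_snp = 0.02,
    alpha_gw = 5e-8, clump_window_bp = 500000,
    # prs
    prs_r2 = 0.1, prs_window_bp = 250000,
    prs_thresholds = prs_threshold_grid(step = 0.01)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste("unknown config fields:", paste(bad, collapse = ", ")))
  utils::modifyList(cfg, over)
}

#' Run the whole endophenotype pipeline on synthetic data
#'
#' Executes, in order: template and cohort simulation, symmetrization and
#' GPA, PLSR covariate adjustment, RV similarity and spectral segmentation,
#' per-segment models, trait fitting with permutation tests, trait
#' selection and effective-test counting, cosine scoring of an unrelated
#' genotyped cohort, per-SNP association with IVW meta-analysis over two
#' cohort halves and distance clumping, and a PRS threshold scan against
#' simulated discovery summary statistics. Every stage draws its seed from
#' the master seed, so a rerun with the same config is identical.
#'
#' @param config A [pipeline_config()] list.
#' @return An `endo_run` list with the stage artifacts (`hierarchy`,
#'   `models`, `traits`, `selected`, `m_eff`, `scores`, `gwas`, `loci`,
#'   `prs_scan`, ...) and a `manifest` tibble recording per-stage
#'   parameters and sizes.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  manifest <- list()
  note <- function(stage, ...) {
    manifest[[length(manifest) + 1]] <<- tibble(stage = stage, !!!list(...))
  }
  seed <- config$seed

  tpl <- make_template(config$p, seed = seed)
  note("template", p = config$p, seed = seed)

  eff_dir <- localized_direction(tpl, center = config$effect_center)

  euro <- simulate_cohort(tpl, n = config$n_euro, effect_size = 0,
                          noise_sd = config$noise_sd, seed = seed + 1)
  parent <- simulate_cohort(tpl, n = config$n_parent_group + config$n_unselected,
                            frac_group1 = config$n_parent_group /
                              (config$n_parent_group + config$n_unselected),
                            effect_direction = eff_dir,
                            effect_size = config$effect_size,
                            noise_sd = config$noise_sd, seed = seed + 2)
  note("simulate", n_euro = config$n_euro,
       n_parent = config$n_parent_group, n_unselected = config$n_unselected,
       effect_size = config$effect_size)

  al_euro <- prep_cohort(euro$configs, tpl$pair_map)
  al_parent <- prep_cohort(parent$configs, tpl$pair_map)
  note("gpa", iterations = al_euro$iterations)

  covs_e <- cbind(as.matrix(euro$covariates[, c("sex", "age", "height", "weight")]),
                  size = al_euro$centroid_sizes, age2 = euro$covariates$age^2)
  covs_p <- cbind(as.matrix(parent$covariates[, c("sex", "age", "height", "weight")]),
                  size = al_parent$centroid_sizes)
  sh_euro <- adjust_covariates(al_euro$shapes, covs_e)
  sh_parent <- adjust_covariates(al_parent$shapes, covs_p)
  note("adjust", covariates_euro = ncol(covs_e), covariates_parent = ncol(covs_p))

  sim <- build_similarity(sh_euro)
  hier <- spectral_hierarchy(sim, levels = config$levels, seed = seed)
  note("segment", levels = config$levels, n_segments = nrow(hier$segments))

  # segments whose parallel analysis retains nothing carry no shape signal
  # and are dropped from trait fitting
  models <- lapply(hier$segments$segment_id, function(sid)
    tryCatch(
      fit_segment_model(sh_euro, hier, sid, pa_reps = config$pa_reps,
                        pa_percentile = config$pa_percentile, seed = seed + sid),
      error = function(e) NULL))
  n_rejected <- sum(vapply(models, is.null, TRUE))
  models <- models[!vapply(models, is.null, TRUE)]
  if (length(models) == 0L) abort("no segment retained any component")
  note("models", n_models = length(models), n_rejected = n_rejected,
       median_k = stats::median(vapply(models, function(m) m$k, 1)))

  traits <- fit_traits(sh_parent, parent$group, models,
                       n_perm = config$n_perm, seed = seed)
  selected <- select_traits(traits, alpha = config$alpha)
  if (nrow(selected) < 2L) selected <- traits   # degenerate null runs
  scores <- score_traits(selected, sh_euro)
  meff <- effective_tests(scores, alpha = config$alpha)
  note("traits", n_perm = config$n_perm, n_selected = nrow(selected),
       m_eff = meff$m_eff)

  geno <- simulate_genotypes(config$n_euro, config$n_snps,
                             block_size = config$block_size,
                             ld_block_rho = config$ld_block_rho, seed = seed + 3)
  causal <- simulate_causal_scores(geno, config$causal_idx, config$h2_snp,
                                   seed = seed + 4)
  # graft the pure genetic component onto the first selected trait's score
  # so the causal SNPs explain h2_snp of that trait exactly
  genetic <- scale(geno$dosages[, config$causal_idx, drop = FALSE],
                   scale = FALSE) %*% causal$beta
  scores[, 1] <- scale(scores[, 1])[, 1] * sqrt(1 - config$h2_snp) +
    scale(genetic)[, 1] * sqrt(config$h2_snp)

  half <- seq_len(floor(config$n_euro / 2))
  scans <- dplyr::bind_rows(lapply(colnames(scores), function(tr) {
    dplyr::bind_rows(
      dplyr::mutate(gwas_scan(scores[half, tr], subset_geno(geno, half)),
                    trait = tr, cohort = "A"),
      dplyr::mutate(gwas_scan(scores[-half, tr], subset_geno(geno, -half)),
                    trait = tr, cohort = "B"))
  }))
  meta <- meta_scans(scans)
  thr <- gwas_thresholds(ncol(scores), alpha_gw = config$alpha_gw)
  loci <- clump_loci(meta, p_threshold = thr$genomewide,
                     window_bp = config$clump_window_bp)
  note("gwas", n_snps = config$n_snps, n_traits = ncol(scores),
       n_loci = nrow(loci))

  disc <- simulate_genotypes(2000, like = geno, ld_block_rho = config$ld_block_rho,
                             seed = seed + 5)
  ss <- make_discovery_sumstats(disc, causal_idx = config$causal_idx,
                                seed = seed + 6)
  kept <- ld_clump(ss, geno, r2_thresh = config$prs_r2,
                   window_bp = config$prs_window_bp)
  prs <- prs_matrix(geno, kept, thresholds = config$prs_thresholds)
  scan <- prs_scan(prs, scores)
  note("prs", n_clumped = nrow(kept), n_thresholds = length(prs$thresholds),
       prs_threshold = config$alpha / meff$m_eff)

  structure(list(
    config = config, template = tpl, hierarchy = hier, models = models,
    traits = traits, selected = selected, m_eff = meff, scores = scores,
    gwas = meta, loci = loci, prs = prs, prs_scan = scan,
    manifest = dplyr::bind_rows(manifest)), class = "endo_run")
}

# restrict an endo_geno to a subset of individuals
subset_geno <- function(genotypes, idx) {
  out <- genotypes
  out$dosages <- genotypes$dosages[idx, , drop = FALSE]
  out$sex <- genotypes$sex[idx]
  out
}

#' @export
print.endo_run <- function(x, ...) {
  cat(sprintf(
    "<endo_run> %d segments | %d traits selected | m_eff %d | %d loci\n",
    nrow(x$hierarchy$segments), nrow(x$selected), x$m_eff$m_eff, nrow(x$loci)))
  invisible(x)
}
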