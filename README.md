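# endoface

Global-to-local facial endophenotypes from dense 3D landmarks, with
quantitative-trait GWAS and polygenic-score follow-up.

## The problem

Subclinical facial shape deviations ("endophenotypes") can mark genetic
susceptibility to disorders such as non-syndromic cleft lip/palate: the
unaffected relatives of affected individuals carry subtle, heritable
facial features. Quantifying those features, and relating them to
genotype, takes a pipeline that spans geometric morphometrics and
statistical genetics. endoface implements that pipeline for researchers
working with corresponded dense-landmark facial data (or any bilaterally
symmetric landmark data):

1. **Shape preprocessing** — reflection via the template's left/right
   pairing map, symmetrization, generalized Procrustes alignment (GPA),
   Mahalanobis-based QC, and PLSR residualization on covariates
   (`reflect_landmarks()`, `symmetrize_landmarks()`, `gpa()`,
   `prep_cohort()`, `qc_scores()`, `adjust_covariates()`).
2. **Data-driven segmentation** — landmark-by-landmark similarity by
   Escoufier's RV coefficient,
   RV = tr(Σxy Σyx) / √(tr(Σxx²) tr(Σyy²)),
   and recursive normalized-cut spectral bisection into a five-level
   hierarchy of 2⁶ − 1 = 63 facial segments; each segment gets its own
   GPA + PCA shape space with Horn's parallel analysis choosing the
   retained dimension (`build_similarity()`, `spectral_hierarchy()`,
   `fit_segment_model()`, `project_segment()`).
3. **Endophenotype traits** — per segment, a one-component PLSR contrast
   of two cohorts yields a unit direction of effect in PC space, tested by
   permutation on R² (10,000 label shuffles, add-one p-values);
   individuals are scored by the cosine distance 1 − cos∠(shape, trait);
   the Li–Ji effective number of independent traits sets the Bonferroni
   level (`fit_traits()`, `cosine_score()`, `score_traits()`,
   `effective_tests()`).
4. **GWAS** — per-cohort OLS of scores on major-allele dosages (X males
   coded 0/2), fixed-effect inverse-variance meta-analysis, ±500 kb
   distance clumping into loci, genome-wide (5×10⁻⁸) and study-wide
   (5×10⁻⁸ / n traits) thresholds (`gwas_scan()`, `ivw_meta()`,
   `clump_loci()`, `gwas_thresholds()`, `annotate_overlap()`).
5. **Polygenic risk scores** — LD clumping of discovery summary statistics
   (r² > 0.1 within ±250 kb), PRS at a grid of inclusion thresholds from
   5×10⁻⁸ to 1, and a regression scan of PRS on endophenotype scores
   (`ld_clump()`, `prs_matrix()`, `prs_scan()`).

A synthetic-data module (`make_template()`, `simulate_cohort()`,
`simulate_genotypes()`, `make_discovery_sumstats()`) generates symmetric
landmark templates, cohorts with smooth latent shape covariance and
planted group effects, LD-structured genotypes and discovery studies with
known causal SNPs, so the entire pipeline is testable end to end without
any external data. `run_pipeline()` chains everything under one config and
one master seed and returns a manifest of every stage.

Results come back as tibbles with `tidy()`, `glance()`, `autoplot()` and
`plot_manhattan()` methods, so they drop straight into dplyr/ggplot2
workflows.

## Worked example

```r
library(endoface)

cfg <- pipeline_config(
  p = 100, n_euro = 200, n_parent_group = 100, n_unselected = 100,
  levels = 3, pa_reps = 40, n_perm = 999, n_snps = 100,
  causal_idx = 15L, h2_snp = 0.2,
  prs_thresholds = c(1e-4, 1e-2, 0.1, 0.5, 1), seed = 42)
run <- run_pipeline(cfg)
run
#> <endo_run> 15 segments | 15 traits selected | m_eff 10 | 1 loci

tidy(run$traits)
#> # A tibble: 15 x 4
#>   segment_id     k    r2 p_perm
#>        <int> <int> <dbl>  <dbl>
#> 1          1    35 0.202  0.001
#> 2          2    33 0.138  0.001
#> ...
```

Three bisection levels give 15 segments (1 + 2 + 4 + 8). The planted
parent-versus-unselected shape shift is detected in every segment that
overlaps it (permutation p = 0.001, the smallest value 999 permutations
can produce), and the 15 correlated trait scores amount to `m_eff = 10`
effective tests, i.e. a Bonferroni level of 0.05 / 10 = 0.005.

```r
dplyr::select(run$loci, lead_snp, pos, best_trait, best_p)
#> # A tibble: 1 x 4
#>   lead_snp    pos best_trait   best_p
#> 1 rs000015 150000 seg1       2.09e-11

dplyr::slice_min(glance(run$prs_scan), min_p, n = 2)
#> # A tibble: 2 x 3
#>   trait    min_p best_threshold
#> 1 seg1  1.53e-10         0.0001
#> 2 seg11 3.03e- 2         0.0001
```

The GWAS meta-analysis recovers exactly one locus, led by rs000015 — the
SNP the generator made causal for the first trait (20% of score
variance) — at p = 2×10⁻¹¹, far beyond genome-wide significance. The PRS
scan likewise ranks that trait first (minimum p = 1.5×10⁻¹⁰ at the
strictest inclusion threshold); all other traits stay near the null.

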