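---
title: "Facial endophenotypes from dense landmarks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial endophenotypes from dense landmarks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

endoface implements a global-to-local pipeline for facial endophenotypes:
dense corresponded 3D landmarks are symmetrized and aligned, the face is
partitioned into a hierarchy of data-driven segments, each segment gets a
principal-component shape space, a group contrast (e.g. unaffected parents
of affected children versus unselected individuals) defines one trait
direction per segment, individuals are scored by cosine distance to those
directions, and the scores feed a quantitative-trait GWAS meta-analysis and
a polygenic-risk-score scan. This vignette explains each model, the choices
behind the defaults, and what the synthetic-data generator does and does
not emulate.

```{r setup}
library(endoface)
```

## Shape preprocessing

Faces arrive as configurations of `p` corresponded quasi-landmarks, with a
template pairing map that matches each left landmark to its right
homologue (midline points pair with themselves). `reflect_landmarks()`
negates the x coordinate and re-indexes through the pairing map, so a
reflected face remains landmark-homologous; `symmetrize_landmarks()`
co-superimposes a face with its reflection (rotation and translation only)
and averages the pair. Working on symmetric configurations concentrates
the analysis on structural shape rather than fluctuating asymmetry.

`gpa()` is a standard generalized Procrustes superimposition: center,
optionally rescale to unit centroid size, rotate each configuration onto
the running consensus, and iterate until the consensus root-mean-square
change falls below `1e-8` (at most 100 iterations). Rotations are
restricted to proper rotations; mirror images are handled explicitly by
the pairing map, never by improper rotations. Scale removal is on by
default and the centroid sizes are exported so facial size can be used as
a covariate downstream. After convergence the solution is rotated onto the
consensus principal axes with a stable sign convention, which makes the
aligned output invariant to how the raw scans happened to be oriented; the
pairwise superimposition inside `symmetrize_landmarks()` skips this step
because there the x = 0 mirror plane is meaningful and must be preserved.

Covariate adjustment uses partial least squares regression
(`adjust_covariates()`): shapes are regressed on the covariate block with
one NIPALS component per covariate, and the fitted effect is subtracted
while keeping the grand mean. With the full component count on full-rank
covariates this is algebraically ordinary least-squares residualization
(the test suite asserts equality against `lm()` at `1e-8`), but the PLSR
formulation degrades gracefully when covariates are collinear: components
are capped at the covariate rank with a warning instead of failing.
Cohorts should be adjusted separately and concatenated afterwards, as
camera systems and covariate distributions differ between collections.

Quality control (`qc_scores()`) computes each face's Mahalanobis distance
to the sample mean in a PCA subspace covering 98% of variance (the
covariance matrix of dense landmark data is singular in full coordinates,
so a reduced space is required for an invertible metric — the choice of
space is a judgment call, flagged as such), standardizes the distances to
Z-scores, and flags faces above `z_threshold = 2` for manual inspection.

## Data-driven segmentation

The similarity between two landmarks is Escoufier's RV coefficient of
their two 3-column coordinate blocks across individuals,

$$\mathrm{RV}(X, Y) = \frac{\operatorname{tr}(\Sigma_{XY}\Sigma_{YX})}
{\sqrt{\operatorname{tr}(\Sigma_{XX}^2)\operatorname{tr}(\Sigma_{YY}^2)}},$$

a scalar in [0, 1] that is invariant to rotations within a block — the
right notion of "these two patches of face co-vary" for 3D coordinates.
`build_similarity()` computes all p² entries at once from the cross-product
matrix of the stacked shape matrix (block Frobenius norms), which keeps
the desk-scale cost trivial.

`spectral_hierarchy()` partitions the face by recursive normalized-cut
bisection: on each segment's similarity submatrix it forms
$L = I - D^{-1/2} S D^{-1/2}$, embeds the landmarks on the Fiedler vector,
and splits by seeded 2-means (10 restarts). Five bisection rounds below
the whole face give $2^6 - 1 = 63$ segments. The bisection method itself
is one of several reasonable spectral variants; recursive two-way cuts
were chosen because they reproduce a binary five-level tree with exactly
63 segments by construction. Spatial contiguity is not enforced — clusters
follow covariance only. Two numerical guards exist: a degenerate Fiedler
embedding (fewer than two distinct values) and any 2-means split that
would starve the remaining subtree (every leaf needs at least
`min_size = 3` landmarks) fall back to a deterministic median split on the
Fiedler embedding. The guard keeps the full tree well-defined on small
synthetic templates; on large templates with smooth covariance the 2-means
split is almost always taken.

## Per-segment shape spaces and parallel analysis

`fit_segment_model()` re-superimposes each segment's landmarks by a fresh
GPA and fits a PCA. The retained dimension comes from Horn's parallel
analysis (100 permuted datasets, 95th percentile — the conventional
settings). One detail matters: Procrustes superimposition concentrates
isotropic noise into $3m - 7$ of the $3m$ coordinates (translation, scale
and rotation are removed), so comparing observed eigenvalues against
plain column permutations of the aligned data over-retains dramatically —
at large n it would keep essentially every constrained dimension of pure
noise. The null datasets are therefore built by column-permuting the *raw*
segment coordinates and pushing each permuted dataset through the same
GPA, so observed and null spectra carry identical constraints. The null
superimposition runs at a loose tolerance (5 iterations), which leaves the
null spectrum unchanged at the resolution the percentile rule uses. With
this matched null the suite verifies both directions: planted rank-3
structure is retained as k = 3, and pure isotropic noise retains at most
one component (usually none, in which case the model is rejected with a
diagnostic — a segment with no supported variation cannot host a trait).

`project_segment()` scores any face in any segment model: the segment is
extracted, superimposed onto the model mean (position, orientation,
scale), centered and multiplied by the orthonormal basis. Scores are
therefore invariant to rigid motion and scaling of the input face. One
caveat is documented and tested: for shapes constructed *directly in model
space* (mean plus a multiple of a basis column), the similarity
superimposition re-scales the synthetic deformation, so exact linear
reconstruction holds under `align = FALSE`; real faces should always use
the default alignment.

## Endophenotype traits

`plsr_contrast()` fits a one-component PLSR of segment PC scores on the
centered binary group label. With a single binary predictor the PLS weight
vector is algebraically a positive multiple of the difference of group
means, so the trait direction equals the oriented, normalized mean
difference — the implementation uses this closed form, and the test suite
checks it against the explicit mean-difference oracle at `1e-6` radians.
The direction is oriented toward group 1 (the parents-like group), and the
pooled effect size is $R^2 = 1 - SS_{res}/SS_{tot}$ across the k
responses.

Significance is assessed by permutation (`permutation_test()`): group
labels are shuffled `n_perm = 10000` times (the conventional depth;
tests use smaller values), with the add-one convention
$p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(1 + n_{perm})$ so p-values are
never zero. Traits with p below 0.05 are selected (`select_traits()`).

An individual's score on a trait is the cosine distance between their
segment PC vector and the trait direction (`cosine_score()`): 0 means the
endophenotypic deviation is fully present, 1 orthogonal, 2 opposite. The
score is scale-invariant in the individual's shape vector — only the angle
matters.

Because segments overlap hierarchically, trait scores are correlated, and
Bonferroni over all of them would be conservative. `effective_tests()`
computes the Li-Ji effective number of tests from the eigenvalues of the
score correlation matrix:
$m_{eff} = \sum_i \left[\mathbf{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor\lambda_i\rfloor)\right]$ (rounded). "Correlation between traits"
is deliberately read as the Pearson correlation of the univariate cosine
scores across individuals — the quantity actually tested downstream;
traits live in different segment PC spaces, so a multivariate
between-space association coefficient would be an equally defensible but
less operational reading. The Li-Ji count only drops below the trait count
when some eigenvalue reaches 2, i.e. under substantial redundancy, which
matches its intended conservatism.

## GWAS and meta-analysis

Genotypes are coded additively as major-allele counts; hemizygous male X
genotypes are coded 0/2 so they share the female 0/1/2 scale
(`code_genotype()`). Each cohort is scanned by simple OLS of the score on
dosage with a t statistic on n − 2 degrees of freedom (`snp_regression()`,
vectorized in `gwas_scan()`; no covariates by design — adjustment already
happened on the shapes). Cohorts are combined by fixed-effect
inverse-variance weighting (`ivw_meta()`): $w_i = se_i^{-2}$,
$\hat\beta = \sum w_i \beta_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$, normal
z. Significant SNPs are clumped into loci by greedy distance clumping
within ±500 kb of each lead (`clump_loci()`), with ties on p broken by
genomic order; loci are disjoint by construction. Thresholds: genome-wide
5e-8 and study-wide 5e-8 divided by the number of traits tested
(`gwas_thresholds()`). `annotate_overlap()` marks loci whose leads fall
within ±500 kb of reference positions, e.g. prior normal-facial-variation
GWAS leads.

## Polygenic risk scores

`ld_clump()` reduces discovery summary statistics greedily by ascending p,
removing SNPs within ±250 kb of a retained index SNP when their dosage
r² exceeds 0.1; the target cohort's own genotypes are the LD reference
(no external panel), and p-ties break by genomic position. `prs_score()`
sums beta × dosage over SNPs passing an inclusion threshold, flipping
betas when the summary effect allele is the dosage's other allele and
dropping (and counting) irreconcilable SNPs; missing dosages impute at
twice the effect-allele frequency. The conventional dense threshold grid
runs from 5e-8 to 1 in steps of 5e-5 (`prs_threshold_grid()`); note the
grid is exposed as a parameter because the conventional range and step
yield 20,001 thresholds — analyses at desk scale use coarser grids and the
realized count is recorded in the run manifest. `prs_scan()` regresses the
PRS (response) on each endophenotype score (predictor) at every threshold,
per cohort; the per-trait minimum p across thresholds is compared against
0.05 divided by the effective number of traits.

## The synthetic-data generator

All tests run on synthetic data with known truth, generated by pure
functions of their seeds.

* **Template** (`make_template()`): a face-like half-ellipsoid lattice,
  mirror-symmetric across x = 0 with a valid pairing involution and a
  small symmetric jitter. Defaults to p = 250 landmarks — enough for a
  five-level hierarchy (which needs at least 96) while keeping every step
  interactive.
* **Cohorts** (`simulate_cohort()`): configurations are the template plus
  latent shape variation, linear covariate effects, an optional localized
  group shift, and isotropic noise. The latent bases are Gaussian random
  fields smoothed over the lattice (bandwidth 0.3 on a face of diameter
  ~2), so nearby landmarks covary — the structure the RV segmentation
  assumes; twelve bases with geometrically decaying scales
  (0.12 × 0.9^k) give a covariance rich enough that recursive bisection
  produces balanced, stable splits. Covariate coefficient fields are fixed
  by the seed so the adjustment stage has a known truth. The group shift
  scale is a free parameter: nothing in the motivating setting pins down
  an absolute effect size for a parent-versus-unselected shape difference,
  so recovery properties are stated at effect_size 1 (about one latent-SD
  of localized displacement).
* **Genotypes** (`simulate_genotypes()`): hard-call dosages under
  Hardy-Weinberg with block LD from a haplotype-copy chain — each allele
  copies its left neighbour with probability rho or redraws at the block
  MAF. This first-order autoregressive dependence gives adjacent-genotype
  correlation *exactly* rho and r² = rho^(2k) at lag k, which a Gaussian
  threshold copula would attenuate unpredictably; controllability of the
  realized r² is what the LD-clumping tests need. `like =` re-uses a
  cohort's SNP panel for independent samples (discovery studies).
  X-chromosome males carry one haplotype, coded 0/2.
* **Phenotypes and discovery studies**: `simulate_causal_scores()` scales
  planted SNP effects to a target variance fraction;
  `make_discovery_sumstats()` dichotomizes a liability at a prevalence
  quantile and score-tests every SNP, yielding the standard
  SNP/CHR/BP/A1/A2/BETA/SE/P table.

What the generator does *not* emulate: real facial covariance (no
anatomy, just smooth fields on an ellipsoid), camera/registration
artifacts, imputation uncertainty (dosages are hard calls), population
structure and relatedness, and linkage between the shape loci and the
liability loci unless planted. Passing tests therefore demonstrate the
statistical machinery — calibration, equivariances, recovery of planted
truth — not anatomical validity on real faces.

## Problem sizes and determinism

The test suite runs at deliberately small sizes: templates of 60–150
landmarks, cohorts of 80–1,000 individuals, 1–2,000 SNPs, permutation
depths of 199–4,999, and 100-permutation parallel analysis, chosen so the
full suite completes in a few minutes while each assertion still has the
statistical resolution it needs (tolerances in the tests are matched to
the Monte-Carlo error of these sizes). The end-to-end demonstration runs
a 250-landmark, 500-face segmentation to the full five levels. Every
stochastic step takes an explicit seed, and `run_pipeline()` derives all
stage seeds from one master seed, so any result in the manifest is exactly
reproducible from its config.

## Known limitations

* The segmentation depends on the seed only through 2-means restarts; the
  bisection tree itself can change under similarity matrices with
  near-tied spectral gaps.
* Trait directions are linear contrasts; curved group differences would be
  summarized by their best linear proxy.
* The Li-Ji count is computed on cosine scores from one reference cohort;
  transferring the Bonferroni threshold to a differently distributed
  cohort changes its meaning.
* `prs_scan()` fits each (trait, threshold) pair independently; no
  optimal-threshold selection or out-of-sample validation is attempted.
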