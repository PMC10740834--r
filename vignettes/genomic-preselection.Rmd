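---
title: "Genomic prediction with GWAS-preselected variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with GWAS-preselected variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

preselblup studies a practical question in animal breeding: when a small
genotyped population must be used to predict breeding values, can variants
preselected from a *large external* GWAS meta-analysis — ranked by p-value or
by in-population ridge-regression effects — improve prediction accuracy over
using the whole SNP panel, and which covariance model uses them best? This
vignette documents the models, the synthetic data they are exercised on, the
numerical choices, and the limits of what the test suite demonstrates.

## The prediction models

All five models are linear mixed models for fixed-effect-corrected
phenotypes $y$ with a general mean $\mu$ and independent residuals
$e \sim N(0, I\sigma_e^2)$. They differ only in the covariance of the random
genetic terms.

* **GBLUP** (baseline): $y = \mu + g + e$ with $g \sim N(0, G\sigma_g^2)$,
  where $G = Z_c Z_c' / (2\sum_i p_i(1-p_i))$ is the VanRaden (method 1)
  genomic relationship matrix over all variants; $Z_c$ is the dosage matrix
  centered by $2p_i$ and $p_i$ the counted-allele frequency computed from
  the data.
* **GFBLUP**: $y = \mu + f + g + e$, adding a second random effect
  $f \sim N(0, G_f\sigma_f^2)$ whose relationship matrix $G_f$ is the plain
  GRM built from the selected ("feature") variants only.
* **TABLUP**: $y = \mu + s_a + e$ with a single trait-specific matrix
  $S_a = M D M' / (2\sum_i p_i(1-p_i))$ over *all* variants, where the
  diagonal of $D$ carries per-variant weights derived from external
  meta-analysis effects (see below).
* **BLUP|GA**: a single kernel $T = \omega S_f + (1-\omega) G$ blending the
  weighted selected-variant matrix $S_f$ (same form as $S_a$ but with only
  the selected variants in $M$) into the plain GRM. $\omega \in [0,1]$ is a
  tuning weight evaluated on the grid $\{0.1, 0.3, 0.5, 0.7, 0.9\}$;
  $\omega = 0$ recovers GBLUP exactly.
* **GTBLUP**: two kernels, $G$ plus the weighted $S_f$, i.e. GFBLUP with
  the feature matrix replaced by its effect-weighted counterpart.

### Kernel weights

The weights on the diagonal of $D$ are squared external meta-analysis
effects (variance scale; absolute values are available via
`weight_fn = "absolute"`). Two normalization decisions matter:

1. **Mean-1 rescaling.** Weights are rescaled so that their mean over the
   variant set entering each matrix is exactly 1. This keeps every weighted
   matrix on the same scale as $G$, so variance components and $\omega$ are
   comparable across models. The rescale is done per matrix: over the panel
   for $S_a$, over the selected set for $S_f$.
2. **Unit invariance of the selected-vs-baseline contrast in $S_a$.** In
   $S_a$, unselected variants carry a baseline weight of 1. A raw squared
   effect is on the trait's (squared) unit scale — about 0.01–0.1 for a
   phenotypic-SD-scaled trait, or thousands for a trait measured in grams —
   so mixing raw squared effects with the baseline would up- or down-weight
   the selected set by an arbitrary unit-dependent factor (on the SD scale
   it effectively deletes the selected QTLs from $S_a$ and collapses TABLUP
   accuracy). We therefore normalize the selected weights to mean 1 *within
   the selected set* before combining them with the baseline: the contrast
   between strong and weak selected variants is preserved, and changing the
   trait's units no longer changes the matrix.

Rank-deficient kernels (routine when few variants are selected) are made
factorizable by adding $\delta \cdot \overline{\mathrm{diag}}$ to the
diagonal, with $\delta$ escalating $10^{-6}, 10^{-5}, \ldots, 10^{-3}$; the
`psd_adjusted` flag records when this happened.

## Variant preselection

Four strategies rank the panel: by external meta-analysis p-value
(ascending) or by the absolute in-population rr-BLUP marker effect
(descending), each applied to a chip-density or sequence-density panel
(`P_top_Chip`, `P_top_WGS`, `G_top_Chip`, `G_top_WGS`). Selection takes
either a top proportion — `round(proportion * panel)` with ties rounded
half away from zero, minimum 1 (this counting rule reproduces published
top-SNP count tables cell by cell) — or all variants with p strictly below
a threshold. Ties in the ranking are broken by genome position for
reproducibility. Selections are nested across increasing proportions by
construction.

rr-BLUP effects are the ridge/BLUP solution with a common prior variance
per marker. The shrinkage ratio $\lambda = c\,\sigma_e^2/\sigma_g^2$ (with
$c = 2\sum p_i(1-p_i)$) comes from single-kernel REML on $G$, and the
effects from the genomic back-solution
$\hat m = (\sigma_g^2/c)\, Z_c' V^{-1} (y - \hat\mu)$, which is
algebraically identical to direct ridge regression and to back-solving the
GBLUP breeding values through $G^{+}$; the test suite verifies both
identities. No per-SNP prior weighting or thinning is applied in this
estimator — it is a plain equal-variance ridge.

## REML

Single-kernel models use an exact 1-D profile REML: the kernel is
eigendecomposed once and the restricted likelihood is profiled over
$\gamma = \sigma_g^2/\sigma_e^2$ ($\mu$ and $\sigma_e^2$ have closed-form
maximizers given $\gamma$), leaving a bracketed search on
$\log\gamma \in [\log 10^{-8}, \log 10^{8}]$ with tolerance $10^{-8}$.
Optima within $10^{-3}$ log units of the bracket edge are flagged as
boundary solutions.

Two-kernel models use average-information REML. The AI system is
ridge-regularized ($10^{-8}$ of its diagonal scale) so that aliased kernels
— whose AI matrix is exactly singular along the unidentifiable direction —
still take Newton-like steps; proposed steps are halved until admissible
and likelihood-non-decreasing, and an EM-REML step
($\sigma_i^2 \leftarrow \sigma_i^2 + \sigma_i^4(y'PK_iPy - \mathrm{tr}(PK_i))/n$)
is the fallback. Components are clamped at $10^{-10}\,\mathrm{var}(y)$;
convergence is declared when the restricted log-likelihood moves by less
than $10^{-6}$ (at most 200 iterations). Because EM approaches a zero
boundary geometrically slowly, a fit in which one genetic component
collapses below $10^{-5}\,\mathrm{var}(y)$ is polished by the exact 1-D
profile solution for the remaining kernel and adopted when it improves the
likelihood. The reported log-likelihood is
$-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ with constants dropped,
identical across both fitters so nesting comparisons are valid.

Prediction for unphenotyped individuals uses the conditional expectation
$\hat g_{\mathrm{test}} = \sum_c \sigma_c^2 K_c[\mathrm{test},\mathrm{train}]\,
V_{\mathrm{train}}^{-1}(y - \hat\mu)$, equivalent to solving the
mixed-model equations with missing phenotypes. Variance components and
$\hat\mu$ are re-estimated inside every training fold; the intercept is
always refit.

## Cross-validation and comparisons

The default plan is 5 repeats of 10-fold cross-validation (50 train/test
evaluations); fold sizes differ by at most one. Accuracy is the sample
Pearson correlation between corrected phenotypes and predicted breeding
values of the held-out individuals, aggregated as a *mean of fold
accuracies* (never a pooled correlation). Model pairs are compared by
two-sided paired t-tests over fold accuracies, matched by (repeat, fold),
starred at p < 0.05 / p < 0.01 with no multiple-testing correction.

Leakage rules: held-out individuals never contribute to variance
components; `G_top` rr-BLUP rankings are refit from the training
individuals inside every fold; `P_top` rankings and all kernel weights come
from the external summary statistics, which derive from independent
populations and are legitimately fold-free. Allele frequencies for kernel
construction use all genotypes (genotypes of selection candidates are
available in practice; phenotypes are not).

## The synthetic-data generator

The generator emulates the study design end to end so nothing needs to be
downloaded:

* **Genotypes.** Biallelic dosages as sums of two haplotypes. Along each
  chromosome, haplotype alleles follow a first-order Markov chain whose
  conditional probabilities are chosen so adjacent variants have
  correlation `ld_rho` while each variant keeps its own marginal frequency
  (drawn uniformly from `maf_range`). This gives analytic control of local
  LD and creates the tag structure preselection needs, at a fraction of the
  cost of a coalescent simulation. Positions are evenly spaced and
  deterministic given the configuration, so cohorts share the study map.
* **Phenotypes.** `n_qtl` causal variants with normal effects, rescaled so
  the realized genic variance equals the target heritability on a
  phenotypic-variance-1 scale; year/season/sex/farm factor levels (5/2/2/11
  by default, mirroring a five-year, two-season, two-sex, eleven-farm
  nucleus design) assigned uniformly with N(0, `fixed_effect_sd`^2) level
  effects.
* **Meta-analysis.** Each cohort is an independent population on the same
  map sharing the same QTL truth; per cohort and variant a simple
  phenotype-on-dosage regression yields an estimate and SE, pooled by
  fixed-effect inverse-variance meta-analysis with two-sided normal
  p-values. Cohorts are generated without missing genotypes and without
  fixed effects (their GWAS is taken to run on pre-corrected phenotypes).

Defaults describe the desk-scale study the package ships with: 500 study
individuals x 5000 variants on 5 chromosomes (5 kb spacing), MAF in
[0.05, 0.5], `ld_rho` 0.5, 30 QTLs at heritability 0.5, 2% missing
dosages, and three external cohorts of 500.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: population structure and relatedness between
study and cohort populations (per-cohort GWAS uses no structure
correction), imputation error, allele-frequency drift between populations,
strand ambiguity (alleles are consistent by construction), X-linked or
multi-allelic variation, and realistic genome-scale LD beyond a first-order
chain. Real-data accuracy magnitudes depend on the population and are not
reproduced; the suite checks exact algebraic identities, parameter
recovery, and qualitative patterns (accuracy rising to a peak near the
top 1–5% and declining toward the all-variant value; architecture-aware
weighting beating GBLUP when the weights carry signal).

## Numerical and design choices

* "SNP call rate < 0.05" filters are read as "missing fraction > 0.05
  removed" (PLINK convention); the literal reading would remove almost
  nothing. MAF uses a strict inequality: MAF exactly at the threshold is
  retained.
* Hardy-Weinberg uses the 1-df chi-square goodness-of-fit test with the
  allele frequency estimated from the sample; monomorphic variants pass
  with p = 1.
* LD pruning is a greedy left-to-right scan keeping the earlier variant of
  a violating pair, with a fixed base-pair window and squared Pearson
  correlation of dosages (r-squared semantics assumed); zero-variance
  variants are treated as uncorrelated.
* Residual missing dosages after QC are mean-imputed (frequency-preserving)
  before any matrix algebra.
* Effect-allele harmonization is by exact (chromosome, bp) match with a
  sign flip when the study's counted allele is the summary table's
  non-effect allele; duplicate summary positions use the first occurrence.
* Factor correction is OLS with one-hot encodings and the first level as
  reference; residuals are reference-level-invariant, and aliased columns
  are dropped with a warning (residuals are unaffected).
* Rounding of printed-table quantities is half away from zero; p-values
  read from files are clamped to (1e-300, 1].
* Problem sizes in the test and acceptance suites are chosen for a
  single-CPU desk run: oracle equivalences on 40–200 individuals,
  parameter recovery on 2000 individuals x 1000 variants over 10 seeds,
  and the proportion-grid pattern on 300 individuals x 3000 variants with
  the accuracy curve averaged over five simulated traits (the top two grid
  cells are near-tied within a single trait).

## Known limitations

The AI-REML fitter handles two kernels (the models here need at most two);
there is no pedigree or single-step matrix, no dominance/epistatic kernels,
no Bayesian whole-genome regression, and no forward (time-split)
validation. LD-aware clumping of hits and conditional/joint selection are
out of scope; selection is purely rank-based. The BLUP|GA $\omega$ is
evaluated on a grid, not optimized continuously.
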