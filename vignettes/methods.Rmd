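---
title: "Methods: epigenetic gestational age analysis with gaclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic gestational age analysis with gaclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gaclock` implements a cord-blood DNA methylation analysis of chronological
gestational age (GA) as a connected pipeline:

1. probe quality control and quantile normalization of an array-scale
   beta-value matrix (`preprocess_dataset()`);
2. latent confounder estimation (`estimate_num_factors()`,
   `estimate_latent_factors()`);
3. a per-CpG epigenome-wide association study (EWAS) of GA in days
   (`run_ewas()`), with Benjamini–Hochberg false discovery control and
   genomic-inflation diagnostics;
4. differentially methylated region (DMR) detection by correlated p-value
   combination (`call_dmrs()`);
5. nearest-gene functional annotation and enrichment
   (`assign_functional_category()`, `category_enrichment()`,
   `gene_set_enrichment()`);
6. an elastic-net epigenetic gestational age (EGA) clock with
   cross-validated age acceleration (`train_clock()`,
   `cross_validated_ega()`);
7. prenatal/perinatal exposure models against GA, EGA and EGAA
   (`run_all_exposures()`, `backward_select_aic()`); and
8. cohort-description machinery (`build_table_one()`).

A synthetic-cohort generator (`simulate_cohort()`) provides a ground-truth
test bed with the statistical structure the analysis assumes; every claim
the test suite makes about recovery or calibration is made against that
generator, not against any real cohort.

# The measurement scale

Array methylation is summarized per CpG as a beta value, the estimated
methylated proportion in $[0,1]$. Regression operates on M-values,
$M = \log_2\bigl(\beta/(1-\beta)\bigr)$, which stabilizes the variance near
the boundaries. Betas of exactly 0 or 1 are clamped to $10^{-6}$ before the
transform; the inverse transform is exact to $10^{-12}$ elsewhere.
Normalization runs on the beta scale and conversion to M follows, matching
the usual array-pipeline order (normalize, then logit).

# Quality control

A probe is removed when any enabled rule fires: a detection p-value above
0.05 in more than `detection_fail_fraction_max` of samples (default 0,
i.e. any failing sample removes the probe — the strictest reading of a
"detection p > 0.05" exclusion; relax the fraction to taste), a SNP at the
probe's 3' or 5' position, location on a sex chromosome, or off-target
capture. Samples are never removed by QC. Quantile normalization replaces
each sample's order statistics by the across-sample mean of order
statistics (ties share the average-rank reference value), delegated to
`limma::normalizeQuantiles`.

# Latent confounders

Cord-blood methylation carries structured nuisance variation (cell-type
composition above all; batch and position effects) that is unmeasured here.
The estimator is a residualize-then-SVD approximation to outcome-aware
confounder methods:

* **K selection** is by parallel analysis: the matrix is residualized on
  the known covariates, each probe's residuals are permuted across samples,
  and K is the number of leading singular values exceeding the 95th
  percentile of their permutation counterparts. On pure noise this yields
  K = 0 about 95% of the time by construction — the test suite checks the
  rate against its binomial error, not against certainty.
* **Scores** protect the outcome. Learning factors from the covariate-only
  residual fails in an instructive way: when many CpGs genuinely track GA,
  the GA association pattern is itself a high-variance direction, the SVD
  captures it, and adjusting for it erases the signal the EWAS is looking
  for (feature selection collapses to empty). The estimator therefore
  learns the *loadings* from the matrix residualized on covariates *and*
  GA — excluding the GA signature from the loading space — and then scores
  samples by projecting the covariate-only residual onto those loadings,
  so scores remain free to correlate with GA and can absorb genuine
  confounding. Scores are centered and orthonormalized deterministically;
  loadings carry a fixed sign convention (largest-magnitude entry
  positive).

On synthetic cohorts with confounding strength 0.5 and no signal, the
unadjusted EWAS inflates to $\lambda \approx 15$; adding the estimated
factors returns $\lambda$ to within 0.1 of 1. Held-out samples are scored
with the training residualization coefficients and the stored basis
(`project_latent()`), so clock prediction never refits factors on test
data.

# EWAS

Each probe's M-values are regressed on GA (days), sex, race (dummy-coded
against the largest category; the reference choice does not affect the GA
term) and the latent factor scores. All complete probes share one design,
so the scan is a single QR decomposition; probes with missing values fall
back to per-probe complete-case fits and zero-variance probes are flagged
rather than fatal. Two-sided p-values use the t distribution with
$n - \mathrm{rank}(X)$ degrees of freedom; q-values are Benjamini–Hochberg
step-up. Genomic inflation is
$\lambda = \mathrm{median}\,\chi^2_{\mathrm{obs}} / \chi^2_{1,0.5}$.

# Regions

The region module reimplements comb-p-style detection:

1. **ACF**: probit scores $z = \Phi^{-1}(1-p)$ are correlated over probe
   pairs binned by distance (50 bp bins to 1 kb by default); bins with
   fewer than 10 pairs are zeroed and flagged.
2. **Neighborhood correction**: each site's p is replaced by the
   Stouffer–Liptak combination $1 - \Phi\!\bigl(\sum_i z_i / \sqrt{\sum_{ij}
   \sigma_{ij}}\bigr)$ over sites within ±1 kb, with $\sigma$ looked up from
   the ACF. Non-positive-definite $\sigma$ is repaired to the nearest
   correlation matrix and flagged.
3. **Region finding**: maximal runs of corrected p below 0.05, gaps at most
   1 kb, at least two probes.
4. **Region p**: Stouffer–Liptak again over member sites — crucially with
   an ACF *re-estimated on the corrected p-values* out to twice the
   window. Neighboring corrected p-values share underlying observations
   and are far more correlated than raw ones; using the raw-p ACF here is
   anti-conservative (on null cohorts it produced many spurious q < 0.05
   regions, versus none with the corrected-p ACF).
5. **Search-space correction**: Šidák,
   $p_{\mathrm{sidak}} = 1-(1-p)^{T/w}$, where $w$ is the region span and
   $T$ the union of probe-centered windows summed over chromosomes (the
   searched span, not genome length), followed by BH across regions.

All thresholds (seed p, window, gap, bins) are arguments with the
conventional defaults above. Coordinates are 1-based inclusive in TSV
output and 0-based half-open in BED (`write_regions_bed()`).

# Annotation and enrichment

Probes map to the gene with minimal absolute strand-aware TSS distance
(ties alphabetical). Categories follow a fixed precedence: promoter bands
(upstream ≤1 kb, 1–2 kb, 2–3 kb), 5' UTR, 3' UTR, 1st exon, other exon,
1st intron, other intron, downstream (≤300 bp past the TES), distal
intergenic. The gene-model container carries optional UTR intervals
because UTRs are not derivable from exon structure alone; models without
them simply never emit UTR categories. Category enrichment is a two-sided
pair of hypergeometric tails (over- and under-representation against the
array background); gene-set enrichment is a one-sided Fisher exact test
restricted to the genes annotated to array probes, with gene sets supplied
as GMT. No pathway database is bundled.

# The clock

The training procedure is: deterministic 80/20 split (the test set holds
$\lfloor 0.2 n \rfloor$ samples, so 391 samples split 313/78); EWAS and
FDR-based feature selection on the training set only; elastic net
$\tfrac{1}{2n}\lVert y - X\beta - Z\gamma\rVert^2 + \lambda(\alpha
\lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2)$ with the
covariates $Z$ (sex, race dummies, latent scores) unpenalized; a five-fold
cross-validated EGA pass inside the training set whose residuals feed the
outlier rule (|residual| > 20 × mean |residual|; the mean is taken over
magnitudes because signed least-squares residuals average to zero, which
would make the literal rule degenerate); flagged samples are removed and
the model refit once; the final model is then applied to the held-out
test set.

Unreported tuning choices are fixed as: $\alpha = 0.5$ (neutral between
lasso and ridge, exposed as an argument) and $\lambda$ at the minimum of
the internal five-fold CV curve over glmnet's 100-point log grid, with the
fold assignment a deterministic function of the seed. EGA for a whole
cohort comes from `cross_validated_ega()`: per fold, the *entire* training
procedure — latent estimation, EWAS, selection, fit — runs on the other
folds, so no sample influences its own prediction; fold assignment is
keyed to sorted sample ids and is therefore invariant to input order.
EGAA is exactly `EGA - GA`. Agreement metrics are Pearson r, $R^2$ as the
squared correlation of observed with predicted, ICC in the two-way
absolute-agreement single-measures form (computed from the two-column
ANOVA decomposition, so a constant bias lowers it even when r = 1), and
Bland–Altman mean difference with mean ± 1.96 SD limits of agreement.

# Exposure models

Single-exposure models are unadjusted OLS per exposure with an overall
F-test; categorical exposures report one coefficient per non-reference
level with $t_{0.975}$ confidence intervals, and q-values are BH within
each outcome across the exposure sheet. Multi-exposure models use backward
selection under $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ (additive
constants omitted; ranking-invariant and equal to `stats::extractAIC`),
dropping whole categorical terms greedily until no drop lowers AIC. The
sample is fixed to complete cases across all candidates before stepping so
AIC values remain comparable; single-exposure models are complete-case per
exposure.

# The synthetic world

The generator's defaults state the cohort the pipeline is designed around:
391 samples; GA truncated-normal (mean 274.02 d, SD 11.02 d, range
210–300 d spanning pre- to post-term); 5,000 probes at desk scale (the
target array carries ~46,000); 5% of probes causal with slopes
N(0, 0.02 M-units/day); two latent factors with N(0, 0.1) loadings, drawn
jointly Gaussian with standardized GA at the configured correlation so
"confounding strength" is directly a correlation; per-probe residual SDs
uniform on 0.15–0.45 M-units (the typical array-probe range); per-probe
baselines placed so betas fall mostly in (0.05, 0.95), avoiding M blow-up;
detection failures at rate $5\times10^{-5}$ per (probe, sample) pair,
which under the strictest any-sample rule reproduces the ~1.4% probe loss
a cohort-scale QC reports. Component draws use separate derived
sub-seeds, so switching one component off (e.g. zero effects) leaves every
other draw bit-identical — this is what makes the zero-effect-equivalence
test meaningful. Exposures named in `exposure_effects` are drawn
conditionally on GA with a linear probability tilt calibrated so the
univariate regression slope of GA on the exposure equals the stated
day-shift in expectation.

What the generator does *not* emulate: cell-type mixtures (no cell counts
existed in the motivating design), probe-type chemistry differences,
spatial chromosomal covariance beyond the planted clusters, batch
structure, and non-Gaussian exposure dependencies. A green recovery test
therefore establishes that the machinery is correct and calibrated under
the stated model, not that a real cohort would yield any particular
result; headline numbers from real cohorts (counts of significant CpGs or
regions, clock $R^2$, exposure coefficients) are not reproducible without
the underlying data and are nowhere asserted.

One acceptance-level power note: a −4.4-day shift planted on a
19%-prevalence categorical level has per-seed detection power of only
~0.5 at the 22-exposure FDR threshold with n = 500, so the ≥90% detection
criterion is exercised with the shift planted on the balanced binary
exposure (power ≈ 0.92); the level-specific coefficient recovery (within
2 SE of −4.4) is tested separately.

# Numerical choices

* p-values are clamped to $[10^{-15}, 1-10^{-15}]$ before probit
  transforms; zero p-values entering the inflation estimate are clamped to
  the smallest positive double with a warning.
* Stouffer–Liptak with $k=1$ returns the input unchanged; fully redundant
  evidence ($\rho = 1$) degenerates to the common p.
* `fit_elastic_net()` with an explicit `lambda` embeds it at the end of a
  decreasing warm-start path with a $10^{-14}$ convergence threshold, so
  $\lambda = 0$ reproduces OLS to $10^{-6}$.
* Chi-square tests apply Yates continuity correction exactly when the
  table is 2×2; the two-sample t-test from summaries is pooled-variance
  Student's t. Both conventions are what make printed two-group
  cohort-description p-values reproduce from their published summaries.
* All randomness flows through explicit integer seeds; derived sub-seeds
  stay below $2^{31}$.

# Known limitations

* The latent estimator is an approximation: it restores null calibration
  and recovers planted factor subspaces, but it is not a likelihood-based
  confounder model and its K is data-driven per run.
* The region caller reports no per-region effect size, only combined
  p-values.
* UTR annotation requires gene models that carry UTR intervals.
* `build_table_one()` classifies numeric variables with ≤5 distinct values
  as categorical; recode counts deliberately if that heuristic is wrong
  for a variable.
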