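---
title: "Models and methods behind imgtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind imgtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`imgtx` implements a case-control imaging-transcriptomics pipeline: from
BOLD time series to voxel-wise ALFF difference maps, to spatially-aware
gene-map association with family-wise error control, to a partition of
genes by cross-dataset replication, and a downstream enrichment suite.
This vignette documents the models, the tunable parameters, the
synthetic-data world the tests run in, the numerical choices, and the
known limitations. Every empirical claim here is one the test suite
computes; nothing is asserted from outside the package.

# The imaging side

## ALFF

The amplitude of low-frequency fluctuations of a voxel's time series is
the mean of the one-sided amplitude spectrum over the 0.01-0.08 Hz band.
After dropping the first `drop_initial_volumes` volumes (default 10, the
usual signal-equilibration convention), the series of length $N$ at
repetition time $TR$ is Fourier transformed; we use the convention

$$ A_k = \sqrt{\tfrac{2}{N^2}\,|X_k|^2}, \qquad f_k = \frac{k}{N\,TR}, $$

excluding the DC and Nyquist bins, with band edges inclusive on the DFT
grid. Any fixed spectral convention cancels in the *standardized* map
(raw ALFF divided by its in-mask mean, so the standardized map averages
exactly 1), and the standardized map is what all downstream inference
consumes. A pure sinusoid of amplitude $A$ on a DFT bin contributes
$A/\sqrt{2}$ to its bin, which is what the amplitude-linearity test pins
down. No temporal filtering is applied before the spectrum; band
selection happens in the frequency domain.

The "global mean" used for standardization is not further specified in
the source conventions (gray matter vs whole brain); we use the analysis
mask, and record that choice here.

## Nuisance regression and framewise displacement

`regress_nuisance()` projects each voxel's series onto the orthogonal
complement of an intercept, a linear trend, and any supplied confound
columns (tissue signals, motion expansions), dropping collinear columns
with a warning. Mean framewise displacement follows the Power
convention: absolute volume-to-volume parameter differences, rotations
converted to arc length on a 50 mm sphere.

## Group inference

The voxel-wise group test regresses the standardized ALFF maps on
`[intercept, group, age, sex, mean FD]`. Because covariate-adjusted
permutation has no single canonical scheme, we use Freedman-Lane: fit
the covariates-only model, permute its residuals, add back the reduced
fit, and recompute the group t. This is the standard
exchangeability-preserving choice; whether the original analyses
permuted labels freely is not documented, so the scheme is a design
decision recorded here. Voxel-level FWE control is max-statistic: each
observed $|t|$ is compared to the permutation distribution of the
maximum $|t^*|$ over the mask. All permutation p-values use the add-one
rule and therefore never reach 0; tests are two-sided, and $t>0$ means
patients above controls.

## Surrogate maps

Spatial correlations between maps (and between gene expression and
maps) cannot be tested against i.i.d. shuffles, because spatial
autocorrelation inflates the null. The surrogate engine generates
randomized maps that preserve the empirical variogram: permute the map,
re-impose autocorrelation by exponential-kernel smoothing over each
point's $k$ nearest neighbours, fit non-negative $(\alpha,\beta)$ by
least squares so the variogram of
$\sqrt{\beta}\,\text{smoothed}+\sqrt{\alpha}\,\text{noise}$ matches the
empirical one, select $k$ from a grid (default
$\{0.1,0.2,0.3,0.4\}\times n$) by residual SSE, and finally rank-map
the original values onto the candidate so every surrogate has exactly
the original value multiset. The variogram uses 25 bins over the near
half of the pairwise-distance range (where it is informative), with a
Gaussian smoother of two bin widths across bins. All of these are
configurable; the defaults are recorded here and used throughout the
tests.

Two properties are tested rather than assumed: on smooth maps the
surrogates' variogram SSE beats plain permutations by an order of
magnitude, and on unstructured maps surrogates are statistically
indistinguishable from permutations.

# The transcriptomic side

Expression preprocessing mirrors the standard donor-atlas pipeline, in
order: (i) probe re-annotation is consumed as an input mapping, not
recomputed; (ii) intensity filtering keeps probes called above
background in at least 50% of samples (inclusive at the boundary);
(iii) RNA-seq-guided probe selection keeps probes correlating strictly
above 0.2 with the gene's RNA-seq profile and picks the argmax (Pearson
by default, Spearman available); (iv) samples are assigned to region
centroids within 2 mm Euclidean distance, others dropped; (v) scaled
robust sigmoid normalization per gene within donor,
$s_i = (1+\exp(-(x_i-\mathrm{med})/(\mathrm{IQR}/1.35)))^{-1}$ then
min-max rescaled to $[0,1]$ (rank fallback when IQR is 0); (vi)
differential stability (DS) per gene as the mean over donor pairs of
the Spearman correlation between region-averaged profiles over shared
regions.

# Association and partition

The phenotype of an expression sample is the mean t-value over in-mask
voxels within a 6 mm sphere of its coordinate (inclusive radius on
voxel centers; on a full-mask 3 mm grid centered at a voxel this is
exactly 33 voxels). Gene-wise Pearson correlations of expression with
this t-vector are tested against a max-|r| null: surrogates of the
t-vector are generated *at the sample coordinates* (equivalent for the
sample-level statistic and far cheaper than voxel-grid surrogates,
which remain available), all gene correlations are recomputed per
surrogate, and the maximum |r*| over genes forms the null. A gene is
significant when its FWE p-value is below alpha *and* its DS is in the
top half of the analyzed universe (the DS filter is
phenotype-independent, so it is applied to observed results only, not
inside the permutation). The "top 50%" quantile is the empirical median
of DS over analyzed genes.

Genes significant in both datasets with the same effect sign are
*clinically insensitive* (replicating); genes significant in dataset 1
but not in that replicating set — including both-significant genes with
opposite signs — are *clinically sensitive*. Cross-disorder overlap
reports, per class, the fraction of its genes significant in a third
dataset's association table.

# Enrichment suite

Over-representation uses the one-sided hypergeometric upper tail with
the sample odds ratio $ad/bc$ (0 for empty overlap, infinity when the
off-diagonal vanishes with positive overlap) — the convention that
prints OR = 0 for zero overlap. Bonferroni families are stated
explicitly: gene sets x stages for temporal enrichment, gene sets x
cell types for the five canonical brain cell types.

Category (GO-like) scores guard against co-expression and spatial
autocorrelation: a category's score is the mean |r| over member genes,
and its null is the same score computed on the ensemble of gene-wise
|r| from surrogate (autocorrelation-preserving) phenotypes — not from
gene-identity shuffles.

The specificity index pSI is operationalized as follows (the original
package's internals are not printed in the sources we follow, so this
is documented as our choice): for gene $g$ and stage $s$, SI is the
mean over other stages $j$ of $g$'s rank (1 = largest) of fold-change
$x_{gs}/x_{gj}$ among all genes; the null permutes gene identities
within each comparison, and pSI is the add-one permutation tail
probability of a smaller-or-equal SI. Non-positive expression is
shifted by $\min + 10^{-6}\max$ before ratios. Ties in fold-changes use
average ranks, so a planted extreme gene can share its rank; its pSI is
minimal among genes but not necessarily exactly $1/(B+1)$. Calibration
on exchangeable matrices and recovery of 10-fold planted elevations are
both tested.

# The synthetic world

The generators are pure functions of (parameters, seed) and emit every
pipeline input. The stated world:

* **Cohorts**: 20 subjects/group by default on a 16 x 16 x 12 grid of
  3 mm voxels, 180 volumes at TR = 2 s (170 retained after the
  10-volume drop, so the DFT grid resolves 0.01-0.08 Hz). Each voxel is
  broadband noise plus in-band sinusoids (0.02/0.04/0.06 Hz) whose
  patient-group amplitude is scaled by `1 + effect_scale * effect_map`.
  Volumes are Gaussian-smoothed at FWHM 8 mm — the smoothing that
  preprocessed BOLD data carry — so t-maps are spatially autocorrelated
  the way real ones are; this matters because the surrogate null is
  *designed* for smooth maps, and with spatially white noise maps it is
  measurably mis-calibrated. Covariates are pure nuisance: age ~
  N(37, 12^2) truncated to [18, 65], sex ~ Bernoulli(0.5), mean FD ~
  |N(0.06, 0.04^2)| mm, and they do not enter the series.
* **Effect maps**: exponential-kernel-smoothed white noise
  (variogram-controllable by construction), standardized; default range
  9 mm.
* **Expression**: 500 genes x 300 samples across 6 donors. Background
  genes are spatially autocorrelated fields with a 6 mm range — chosen
  so the desk-scale domain (~48 mm) keeps the domain-to-correlation-
  length ratio of real cortex-wide transcriptomic data (~10-25); a
  longer range would collapse the effective sample size of gene-map
  correlations and make gene-wise inference meaningless at this scale.
  Each gene mixes a donor-shared and donor-specific field so DS varies;
  signal genes are `rho * z(effect at coords) + sqrt(1-rho^2) * field`
  with high donor-shared weight. Three probes per gene: a low-noise
  best probe, a noisier probe (a fraction planted to fail the intensity
  filter), and an anti-correlated probe the RNA-seq step must discard.
  Region structure uses 34 parcels, the Desikan-Killiany cortical
  count.
* **Annotations**: random categories plus one planted to equal the
  signal genes; a down-regulated DEG list seeded with signal genes; the
  truth's five cell-type marker sets; a positive genes x stages matrix
  with 10-fold elevation of stage-specific genes.

What a green test does *not* establish: the generators contain no
scanner artifacts, motion structure, hemispheric asymmetry, or
donor-specific coverage gaps; covariates do not actually confound; and
expression noise is Gaussian. Calibration and recovery results
therefore validate the statistical machinery, not robustness to real
acquisition pathologies.

# Numerical choices

* Permutation p-values: add-one rule everywhere, so p is never 0 and
  never below `1/(B+1)`.
* Constant voxels in the group test get t = 0, p = 1; zero-variance
  genes get r = 0, p = 1 and a flag; zero-variance phenotypes are
  errors.
* The chi-square op is the plain Pearson statistic without continuity
  correction (df = 1), matching the printed worked examples.
* Mann-Whitney uses the tie-corrected normal approximation, signed so
  z > 0 when the first sample is stochastically larger; Lilliefors
  p-values come from a Monte-Carlo table (10^4 draws by default),
  cached per sample size within the session.
* Sphere inclusion is `<= radius` on voxel centers; boundary-sitting
  voxels are in.
* Bonferroni is `min(1, p * family)` with family sizes stated at the
  call.

# Design decisions taken where the design was open

* **Covariate permutation scheme**: Freedman-Lane (see above).
* **Association surrogates at sample coordinates**, not on the voxel
  grid: the null for the sample-level statistic only needs the sampled
  t-vector's autocorrelation; voxel-grid mode exists behind the same
  API for users who want it.
* **Multiple-testing in the association**: max-statistic FWE over
  genes (the permutation analogue of FWE). An additional Bonferroni
  switch on top of permutation p-values exists but is off by default:
  the methods description we follow specifies the max-statistic
  construction, and stacking both corrections double-counts.
* **DS filter after significance** with the median as threshold; the
  null does not recompute the filter because DS does not depend on the
  phenotype.
* **Criterion-level null for association FWER**: null *expression*
  against an effect-bearing t-map. The association test's null
  hypothesis concerns genes conditional on the observed map; the
  fully-null cohort world is exercised separately by the group-test
  calibration.

# Known limitations

* Variogram-matched surrogates guarantee second-order isotropic
  structure, not the full covariance. When the phenotype's spatial
  structure lives on a different basis than the expression fields
  (e.g., spatially *white* voxel noise maps vs kernel-smoothed gene
  fields), the max-|r| null is conservative: we measured
  family-wise rates near 0-2% in the all-null (unsmoothed-map) world.
  With realistically smoothed maps the test is calibrated; this is a
  property of the surrogate family itself, shared with its reference
  implementations.
* pSI here is a documented operationalization, tested for calibration
  and planted-signal recovery, not for bit-equality with the original
  package.
* No NIfTI I/O: the execution environment provides no R NIfTI reader,
  so images are in-memory arrays with plain-text serialization; all
  geometry uses an isotropic-voxel affine.
* No cluster-level correction, TFCE, fALFF, hemisphere mirroring, or
  surface-based sampling.
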