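---
title: "Linking seed-connectivity interactions to brain gene expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking seed-connectivity interactions to brain gene expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(txnimage)
```

`txnimage` implements an analysis chain used in imaging-transcriptomics
studies of brain-stimulation interventions: per-subject seed-based
functional-connectivity maps, a voxelwise group x timepoint interaction test
with Monte-Carlo cluster-extent correction, behavioral composites and
covariate-adjusted correlations, gene-wise association of regional
connectivity change with spatial gene expression under a spatially
constrained permutation null, and degree-based hub analysis of the
candidate-gene protein-protein interaction (PPI) network. This vignette
documents the models, the tunable parameters, the synthetic generators the
test suite runs against, and the numerical choices made where the design was
genuinely open.

## Seed-based connectivity

Each scan is reduced to a Fisher-z connectivity volume against a spherical
seed (default: left angular gyrus, MNI (-45, -67, 38), radius 6 mm — 33
voxels on a 3 mm grid). For each voxel time series $y_v(t)$ and the mean
seed-sphere series $s(t)$, both residualized on the confound columns (six
motion parameters plus white-matter and cerebrospinal-fluid means, intercept
always included),

$$ r_v = \mathrm{cor}(y_v, s), \qquad
   z_v = \operatorname{atanh}(r_v) = \tfrac12 \log\frac{1+r_v}{1-r_v}. $$

Numerical choices:

* $r$ is clipped to $\pm(1 - 10^{-7})$ before `atanh` so $z$ stays finite;
  the bias is negligible (the clip only binds for numerically exact
  correlations).
* Voxels with zero residual variance (outside-brain padding) are set to
  $z = 0$ and flagged instead of erroring, so every subject keeps a common
  grid. "Zero" is judged relative to the series norm
  ($\mathrm{sd} \le 10^{-8}\,\lVert y \rVert$), since exact zeros do not
  survive floating-point projection.
* Collinear confound columns are dropped with a warning (QR rank detection)
  rather than failing the scan.
* Upstream preprocessing (slice timing, realignment, normalization,
  smoothing, band-pass filtering, initial-volume removal) is out of scope;
  inputs are assumed already preprocessed, and the synthetic generator
  produces band-limited series directly (temporally smoothed noise).

## Group x timepoint interaction

With two groups and two timepoints per subject, the mixed-ANOVA interaction
has a closed form: it equals the squared two-sample $t$ statistic on
per-subject difference scores $d_i = z_i^{\text{follow}} - z_i^{\text{base}}$,
on $df = (1, n_1 + n_2 - 2)$. The package uses this difference-score
identity rather than a generic mixed-model fitter: it is exact for the 2x2
design, fast enough to run voxelwise, and is verified in the test suite
against a general linear model with subject dummy coding to $10^{-8}$. The
group main effect is the two-sample $F$ on subject means, and the time main
effect tests the unweighted mean of the group difference means against the
pooled difference variance.

Family-wise error over voxels is controlled by AlphaSim-style cluster-extent
correction:

1. Noise smoothness is estimated from the interaction residuals (difference
   maps minus their group means) with the variance-of-differences
   estimator: per axis, the lag-1 neighbour correlation
   $\rho = 1 - \mathrm{var}(\Delta)/(2\,\mathrm{var})$ gives
   $\mathrm{FWHM} = dx\sqrt{-2\log 2/\log\rho}$, floored at the voxel size.
2. Gaussian noise is simulated on the mask grid, smoothed to that FWHM
   (variance-preserving kernel), thresholded two-sided at the
   cluster-forming $p$ (default 0.05), and the maximum cluster size is
   recorded per iteration (default 1000 iterations, seed logged).
3. The extent threshold is the ceiling of the $(1-\alpha)$ quantile of the
   max-cluster-size null; clusters at least that large survive. With
   $\alpha \ge 1$ the threshold degenerates to 1 voxel (everything passes).

Open choices and how they were fixed: cluster connectivity defaults to 18
(a common volumetric choice; 6 and 26 are available because published
descriptions of this correction rarely state the rule); the F map is
thresholded at its upper $p$ quantile, which matches the two-sided
threshold used in the null simulation; the iteration count and seed are
recorded in the result. The extent threshold is always a dataset-specific
output — published mm^3 values are not constants to reuse.

## Behavioral composites and adjusted correlations

The episodic-memory composite converts each test's raw scores to z-scores
using the mean and SD of all subjects with both sessions pooled — one
reference scale, so pre and post values stay comparable — and sums the four
tests with equal weight. A zero-variance test is an error that names the
test.

The sleep-quality index is the first principal component of the five
standardized sleep scales (higher raw totals mean worse sleep on all five).
Two conventions had to be fixed:

* **Orientation.** PC1 signs are arbitrary; the package orients PC1 so the
  loading on the insomnia-severity scale is negative, making higher scores
  mean better sleep. The median split then sends *strictly below median* to
  the low-quality group, which is the semantically consistent reading.
* **Ties.** At-median subjects go to the high-quality group. With an even
  cohort and distinct scores this yields two equal halves (23/23 at
  $n = 46$).

Covariate-adjusted correlations residualize both variables on the
covariates plus an intercept and correlate the residuals; $p$ comes from the
$t$ distribution on $n - k - 2$ df. This residualized Pearson correlation
is identical to the partial correlation, so it satisfies both "Pearson with
covariates" and "partial correlation" readings of the procedure. Collinear
covariates (residual norm below $10^{-12}$ of the centred norm) are an
error, not a silent zero.

## Transcription-neuroimaging association

Expression samples are retained when their MNI coordinate falls inside a
mask voxel or within a tolerance (default 2 mm) of a mask-voxel centre,
accommodating coordinates digitized on a different grid. The imaging value
per sample is the mean of the cohort-level connectivity-change summary
(mean over subjects of follow-up minus baseline z) in a sphere at the
sample coordinate; radius 6 mm matches the seed-sphere scale, and radius 0
reads the containing voxel. Gene-wise Pearson correlations across retained
samples are corrected with Benjamini-Hochberg; a gene is significant when
its adjusted q-value is at most the threshold (default 0.001), which is
exactly the step-up rule $p_{(i)} \le i\,q/m$.

### The spatially constrained null

Smooth imaging maps correlated with spatially autocorrelated expression
produce far more nominally significant genes than independent sampling
would — the effective sample size is the number of independent spatial
patches, not the number of samples. The package therefore tests the
*count* of significant genes against surrogate imaging vectors that
preserve both the marginal distribution (exactly, by rank-remapping onto
the observed values) and the spatial autocorrelation (approximately, by
variogram matching) — a volumetric analogue of spin-test surrogates. Each
surrogate permutes the values, smooths the permutation with a
distance-kernel, mixes in a white component, and rank-remaps; the kernel
bandwidth and mixing weight are chosen once per dataset by minimizing the
mean absolute deviation between surrogate and observed binned variograms
over a small grid (10 pilot permutations per candidate). A plain-shuffle
scheme is available for comparison (`surrogate = "shuffle"`), and the test
suite demonstrates on densely sampled autocorrelated data that plain
shuffles systematically understate the null count — the reason the
constrained null exists. The permutation p-value uses the add-one
estimator $p = (k+1)/(n+1)$.

Degenerate geometry (all samples coincident) falls back to unconstrained
permutation with a warning. The surrogate scheme needs at least 20 samples
for variogram fitting, and a reportable permutation p needs at least 100
surrogates.

## PPI networks

Edge tables follow the STRING dialect: scores above 1 are integer-scaled
and divided by 1000; symmetric duplicates merge keeping the maximum score;
self-loops are dropped. The background graph is loaded at score >= 0.7
("high confidence"), the candidate subnetwork re-filters at >= 0.9 and
removes isolated nodes — membership in the "interconnected network" is
degree >= 1 at the stricter threshold, the only operational definition that
maps a candidate list to a connected-node count. Edge enrichment uses an
explicit random-gene-set null: equally sized node sets drawn uniformly from
the graph background, add-one p-value (an exhaustive enumeration mode
exists for toy graphs and is checked against full subset enumeration).
This is deliberately *not* the server-side background model of the STRING
web service, which is not reproducible from published descriptions; the
null here is explicit and seedable. Hubs are the top 10% of nodes by
degree, ties broken lexicographically for determinism.

## What the synthetic generators emulate

**Cohort scans.** Each scan is a shared, temporally smoothed seed time
course projected onto the grid with a voxelwise coupling weight $w$, plus
spatially and temporally smoothed unit-variance Gaussian noise, plus
confound leakage (the generated motion/WM/CSF series enter the voxel
signals with random small weights, so nuisance regression is
consequential). With unit noise the analytic connectivity is
$r = w/\sqrt{w^2+1}$, which makes the functional-connectivity ground truth
closed-form — the test suite checks the mean z-map against it. The
interaction is planted by shifting each cluster's coupling at follow-up so
the subject-level z-change is $+d\sigma$ in the low-sleep-quality group and
$-d\sigma$ in the high-quality group (a pure interaction), where $\sigma$
combines the analytic measurement noise of a z estimate
($\sqrt{\gamma/(T-3)}$, with $\gamma$ the variance inflation from temporal
autocorrelation) and an equal-sized subject-heterogeneity term. Defaults:
23 subjects per group, 170 time points, 3 mm voxels, 6 mm noise FWHM, one
cluster of radius 7.5 mm at $d = 1.2$.

Phenotypes use the published cohort's scale: sleep-scale means/SDs per
group at the magnitudes reported for low/high-sleep-quality cognitive
impairment cohorts (e.g. insomnia-severity 10.2 +/- 4.0 vs 2.6 +/- 1.6),
plus a shared severity latent that gives the scales realistic
inter-correlation. Memory tests get group-shared mean improvements;
the *cross-subject* variation of the change tracks the within-group
variation of the planted connectivity change with latent correlation
`memory_assoc_r` (default 0.55, set so the composite-level partial
correlation lands near 0.5, the magnitude such studies report). Tracking
the within-group variation is deliberate: the behavioral stage partials out
sleep status, so only within-group signal is recoverable by construction.

**Expression.** Samples are placed uniformly inside mask voxels; per-gene
noise is distance-kernel-mixed white noise (Gaussian autocorrelation,
default length 5 mm) plus per-donor intercepts (default 6 donors, SD 0.3),
normalized to unit variance. Planted genes are
$r\,t + \sqrt{1-r^2}\,\varepsilon$ against the standardized target values
at the sample coordinates, so their empirical correlation is $r$ within
sampling error. Because the planted association lives at the sample
coordinates, recovery tests read the map there (radius 0); the sphere
average is for cohort-level summary volumes. Test fixtures place 300
samples in a 72 mm box (about 1240 mm^3 per sample), comparable to
atlas sampling density after mask restriction; at this spacing-to-
autocorrelation ratio, gene-level false positives stay near the nominal
Benjamini-Hochberg rate, which is what the null-calibration tests assert.

**PPI background.** Erdos-Renyi graphs with uniform scores on 0.4-1.0
(integer dialect) and an optional planted dense module.

**What is not emulated:** hemodynamic response functions, physiological
noise, motion artefacts beyond linear confound leakage, multi-echo
acquisition, donor-specific probe noise, and any probe-level expression
preprocessing — the generator emits an already-normalized matrix. Passing
tests therefore certify the statistical machinery under the stated
generative assumptions, not robustness to real acquisition artefacts.

## Calibration designs and problem sizes

The suite's calibration checks run at sizes chosen to keep the full run in
minutes while leaving the Monte-Carlo error bands meaningful:

* Voxelwise null calibration uses $d = 0$ cohorts with spatially
  *independent* noise so the binomial +/- 3 SE band around the 5% rate is
  exact; with smooth noise the voxel tests remain calibrated but the
  binomial band would not apply.
* Family-wise calibration simulates 500 null interaction datasets on a
  12^3 mask at the design smoothness by drawing per-subject difference
  maps directly — the sufficient statistic for the interaction stage —
  and checks that the extent-thresholded false-positive rate stays in
  [0.03, 0.07].
* Gene-recovery runs use 2000 genes, 50 planted at $r = 0.8$, 300 samples,
  500 surrogates; end-to-end cluster recovery uses 12 subjects per group
  on a 12^3 grid with 100 time points.

## Known limitations

* The difference-score ANOVA is exact only for the 2x2 design; more
  timepoints or groups need a general fitter.
* The smoothness estimator assumes a Gaussian autocorrelation shape;
  heavy-tailed spatial kernels bias the FWHM.
* The Monte-Carlo extent simulation thresholds Gaussian fields while the
  interaction map is an F(1, df) field; at moderate df the cluster geometry
  is close but not identical, which is part of why the family-wise band is
  checked empirically.
* Variogram matching is approximate; surrogate quality is asserted at 20%
  integrated absolute deviation, and bandwidth selection can be unstable
  for very few samples (< 20 samples falls back with an error).
* The random-gene-set PPI null conditions only on set size, not on degree;
  degree-matched nulls would be stricter for hub-heavy candidate sets.
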