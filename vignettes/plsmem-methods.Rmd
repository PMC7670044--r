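---
title: "Methods: simulating and analyzing payoff-manipulated recognition memory with PLS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing payoff-manipulated recognition memory with PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsmem)
```

## The problem

In a recognition-memory scan, a participant sees studied ("old") and
unstudied ("new") words and classifies each. Two manipulations shape the
decision: *study repetition* (items studied once, 1x, vs three times, 3x)
changes memory strength, and a *payoff scheme* (more points for correct
"old" responses in incentivize-old runs, for correct "new" responses in
incentivize-new runs) changes the retrieval goal and hence the response
criterion, leaving sensitivity largely untouched. The imaging question is
which distributed networks track repetition versus "targetness" — whether
an item class is the rewarded target of memory search — and how a
hippocampal seed's functional connectivity changes with targetness.

Because raw data for such studies are typically unavailable, the package
pairs every analysis with a generator that emulates the design and its
statistical structure, so the full pipeline — design, behavior,
signal-detection statistics, GLM, task PLS, seed PLS, permutation and
bootstrap inference, peak tables — can be exercised and validated against
planted ground truth.

## Experiment generator

`design_params()` encodes the design: a 512-word pool in 8 lists of 64
(half concrete, half abstract), a 256-word study list (half 1x, half 3x),
and 8 test runs of 64 words each (16 1x, 16 3x, 32 new, balanced over
categories) plus 4 null events, with 500 ms fixation, 3000 ms word
presentation, and inter-trial intervals jittered uniformly in 2000–6000 ms.
Half the runs are incentivize-old, half incentivize-new. Study status of
the lists swaps across counterbalance ids, so each word is studied in
exactly half of a two-id cycle. Words are synthetic tokens (`w0001`, ...):
lexical matching (frequency, concreteness) matters for stimulus
construction but not for any statistic computed downstream, so only the
list structure is modeled. Word-to-run allocation is uniformly random
within the cell counts; the original allocation rule beyond randomization
is not specified anywhere, and no downstream statistic depends on it.

## The simulated observer

`sdt_params()` supports two parameterizations.

* **Rate**: each (run type × item type) cell has a probability of an "old"
  response; defaults are the published group means (incentivize-old hits
  0.74/0.93 and CRs 0.71; incentivize-new hits 0.63/0.86 and CRs 0.83).
  Between-subject heterogeneity is a Gaussian jitter (SD 0.25) on the
  probit scale. Plain jitter would shrink the expected cohort mean toward
  0.5 by the factor $1/\sqrt{1+\sigma^2}$, so the latent mean is scaled by
  $\sqrt{1+\sigma^2}$, making the population cohort mean equal the
  requested cell probability exactly. The jitter SD was chosen so the
  simulated standard errors of cell means (~0.01–0.02) are of the same
  order as the published ones (~0.02–0.03).
* **SDT**: an equal-variance Gaussian model. Old items evoke strength
  $N(d', 1)$, new items $N(0, 1)$; the observer answers "old" when
  strength exceeds $\lambda = d'_{\mathrm{ref}}/2 + c$ with
  $d'_{\mathrm{ref}}$ the run type's mean sensitivity, so $c = 0$ is the
  unbiased point and the payoff manipulation acts purely on $c$ (negative
  = liberal). This parameterization matches the estimators used in the
  analysis stage, so criterion-shift recovery can be tested directly.

Response times are lognormal with condition-specific means calibrated to
the published correct-response RTs and a log-scale SD of 0.3 (a typical
single-trial RT dispersion); correct and incorrect trials share the
condition's RT distribution for simplicity. Null trials produce a key
press but no memory decision and never enter the response table.

## Behavioral statistics

* Hit and correct-rejection rates per subject × run type × item type; RT
  means over correct trials only (`score_responses()`).
* $d' = z(H) - z(F)$ and criterion $c = -\tfrac12[z(H) + z(F)]$
  (`sdt_measures()`), with hit rates collapsed over 1x and 3x items
  (trial-weighted, which equals the plain mean at the balanced counts).
  Both sign conventions for $c$ circulate in the literature; the default
  here is the one under which liberal responding in the incentivize-old
  condition yields negative $c$, consistent with how such studies report
  it, and `sign_convention = "literal"` exposes the opposite sign. Rates
  of exactly 0 or 1 are clamped by the count-aware $1/(2N)$ rule before
  the inverse-normal transform (the log-linear alternative was rejected as
  it perturbs all cells, not just degenerate ones). Group-level $d'$ and
  $c$ are means of per-subject values, not statistics of group-mean rates:
  the two differ by Jensen-type gaps of ~0.1 at these rates, and
  per-subject averaging is what paired tests require anyway.
* Paired $t$ with Cohen's $d_z = t/\sqrt{n}$ (`paired_t()`); the
  zero-variance degenerate case errors rather than returning 0/0.
* TOST equivalence (`tost_paired()`) from summary statistics:
  $t_L = (d_z + b)\sqrt{n}$, $t_U = (d_z - b)\sqrt{n}$, one-sided $p$ with
  $n-1$ df; the binding test is the larger $p$. The default bounds are
  $b = 0.50$ (medium effect) and, where a "large" bound is wanted,
  $b = 0.80$ following Cohen's convention.
* Two-way within-subject ANOVA (`rm_anova_2way()`), classical
  sums-of-squares partition with each effect tested against its
  subject-interaction term and partial
  $\eta^2 = SS_e/(SS_e + SS_{err})$. No sphericity correction is applied
  (none is needed for the 2-level factor; the 3-level factor would need
  one in confirmatory use). The implementation is cross-checked against
  `stats::aov()` with an `Error(subject/...)` stratification in the test
  suite.

## Hemodynamics and GLM

The original analysis convolved stimulus onsets with an AFNI "block
function" whose parameters are not published; the package substitutes the
canonical double-gamma HRF (gamma densities with shape/rate 6/1 minus
16/1 scaled by 1/6, unit peak, peak near 5 s, shallow undershoot) because
it is standard, closed-form, and testable. `build_design_matrix()`
convolves per-condition boxcars (word duration) with the kernel on a
microtime grid (TR/16), scales by the grid step so amplitudes are
resolution-invariant, samples at scan times, and appends an intercept and
(by default) a linear drift regressor. No temporal filtering or
autocorrelation modeling is attempted — preprocessing is out of scope and
the simulator generates white noise. `estimate_betas()` is ordinary least
squares per voxel; `glm_condition_betas()` averages run-wise betas per
condition, mirroring per-subject condition images.

## Condition-image generator

`simulate_condition_images()` produces the subjects × conditions × voxels
array that all PLS analyses consume:

$$X[s,c,\cdot] = \mu + \sum_l a_l\, v_l[c]\, u_l + \text{subject offset}
  + \text{couplings} + \varepsilon$$

with unit-norm task profiles $v_l$ and spatial maps $u_l$ (Gaussian blobs
rasterized on the grid, giving realistic local maxima for peak tests),
voxelwise subject offsets shared across conditions (so mean-centering
removes them, exactly the assumption task PLS makes), and i.i.d. Gaussian
noise. Seed couplings add a standard-normal latent factor to a seed
neighborhood and a correlated factor to a coupled voxel set; the planted
correlation is inflated by the closed-form attenuation factor implied by
the generator's own noise and subject-offset variance, so the *realized*
cross-subject correlation equals the requested `r` — the generator's
contract is the realized statistic, not an internal parameter. The default
grid is 10×10×10 voxels at 2 mm (a desk-scale stand-in for an MNI-like
space); all code paths are grid-size agnostic.

## Task PLS

Mean-centered task PLS operates on the k × V matrix of condition means
minus the grand mean (`mean_center()`), decomposed by SVD
(`pls_svd()`): each latent variable (LV) is a singular value (covariance
accounted for), a unit task-salience profile, and a unit voxel-salience
image; brain scores are projections of each subject-condition image onto
the voxel saliences. Choices made where practice varies:

* SVD of the **condition-mean** matrix, not the full stacked deviation
  matrix — the standard behavior of mean-centered task PLS toolboxes and
  the only variant whose LV count (≤ k−1) matches the condition-profile
  interpretation used here.
* **Covariance, not correlation**: no voxelwise variance normalization
  before the SVD.
* **Deterministic sign**: each LV is flipped so its largest-magnitude
  voxel salience is positive (the SVD sign is arbitrary; tests need
  reproducibility).
* Unweighted condition means (the design is balanced).
* The repetition analysis pools 3x hits and 1x hits over run types by
  default (2 conditions); the targetness analysis contrasts 1x hits of the
  rewarded class plus CRs of the rewarded class against the complement.
  Unpooled 4-condition variants are available with a grouping attribute.

## Seed PLS

`seed_pls()` extracts seed activity as the mean condition beta over a
3×3×3 voxel neighborhood (27 voxels, clipped at volume edges), correlates
it with every voxel across subjects within condition, and decomposes the
stacked k × V correlation matrix with the same SVD conventions. Decisions:

* Condition **betas** are the primary seed input; a peristimulus-window
  path exists for time-series input, averaging the peak and adjacent
  timepoints of an 8-TR window (default TRs 3–5, i.e. 4–8 s post onset,
  bracketing the canonical HRF peak — which timepoints the original
  toolbox averaged is not published).
* Correlations are **not Fisher-z transformed** before the SVD (toolbox
  convention); `fisher_z = TRUE` is available.
* Because the seed's own neighborhood correlates near 1 with itself in
  *every* condition, the first seed LV always carries a large
  condition-shared component; at k = 2 and n = 14 the permutation test
  consequently has limited power for connectivity differences, and the
  bootstrap ratio map is the sensitive instrument for localizing coupled
  voxels. The analysis drivers show exactly this behavior.

## Permutation and bootstrap inference

* **Permutation** (default 500): condition labels are shuffled *within
  subject* — subjects are the exchangeable blocks in a within-subject
  design; a fully unrestricted row permutation is available behind a
  flag since the original description ("rows randomly reordered") does
  not disambiguate. Permuted singular values are compared to observed
  ones rank for rank, and $p = (r+1)/(n_{perm}+1)$ (add-one smoothing:
  valid under exchangeability, never exactly zero). An LV is significant
  at $p < 0.05$.
* **Bootstrap** (default 100): subjects are resampled with replacement and
  the analysis recomputed — including the correlation matrix in seed PLS,
  since correlations are subject-level statistics. Replicate saliences are
  aligned to the original LVs by an orthogonal Procrustes rotation of the
  task-salience basis (resolving sign/rotation indeterminacy; plain sign
  flips would suffice only at k = 2). The bootstrap ratio
  BSR = (salience × singular value) / bootstrap SE is treated as
  approximately a z score and thresholded at |BSR| > 3 (≈ p < 0.001).
  Degenerate resamples with a single unique subject are redrawn and
  counted; zero-SE voxels get a signed infinite BSR, are included in
  masks, and are reported via a message.
* **Peaks**: local maxima of |BSR| in the 26-neighborhood above threshold,
  greedily selected by decreasing |BSR| with a 10 mm exclusion radius and
  lexicographic tie-breaking; coordinates are reported in mm through the
  grid affine. Cluster-extent rules are not used (the original reporting
  rule is unpublished; a documented deterministic rule was preferred).

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle: design
counts exhaustively; SDT formulas against direct inverse-normal
arithmetic; the TOST statistics against the published worked example
(binding t of 0.89 at bound 0.50 and 2.01 at 0.80 for $d_z=-0.26$,
n = 14); the ANOVA against `aov()`; two-condition voxel saliences against
the normalized difference-map oracle ($10^{-10}$); correlation maps
against a brute-force Pearson oracle ($10^{-12}$); SVD energy and
orthonormality identities ($10^{-10}$); GLM recovery exactly (noise-free)
and at SNR 1 ($r > 0.95$).

Statistical calibration runs at deliberately desk-scale sizes chosen to
keep the full suite in the low minutes while leaving clear margins:
permutation type-I error on 200 pure-noise datasets of 40 voxels with 100
permutations each (rejections compared to the exact null rate 5/101 of
the smoothed test via its 99% binomial interval); planted-LV recovery on
a 1000-voxel grid at signal-to-noise 3 — defined as the ratio of the
planted pattern's Frobenius norm to the expected noise norm
$\sigma\sqrt{V/n}$ of the centered condition-mean matrix — over 20 seeds
(|r| > 0.9); seed-coupling detection at realized r = 0.8 with 14 subjects
over 20 seeds (≥ 80% of coupled voxels flagged); bootstrap SE scaling
consistent with $n^{-1/2}$ (log–log slope within ±0.2 of −0.5).

## What the synthetic data do and do not show

The generator reproduces the design's counts and timing, criterion-shift
behavior, cohort-level rate calibration, and the low-rank-plus-noise
structure that PLS assumes, with planted ground truth for patterns and
couplings. It does **not** emulate spatial autocorrelation from smoothing,
physiological or motion artifacts, hemodynamic variability across regions,
non-Gaussian noise, or anatomically realistic geometry. Passing tests
therefore certify the *statistical machinery* — estimators, resampling,
thresholds, bookkeeping — under the stated generative model, not the
reproducibility of any specific published activation coordinates, which
would require the original raw data.
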