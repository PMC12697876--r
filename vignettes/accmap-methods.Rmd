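---
title: "Methods: activation mapping and behavioral analytics in accmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation mapping and behavioral analytics in accmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accmap)
```

`accmap` quantifies how a chronic orofacial-pain condition reorganizes
brain-wide activity and spontaneous behavior in mice. It covers five
analysis surfaces — forward-model activation mapping of region-wise FOS
counts, computational-ethology summaries of labeled behavioral bouts,
deterministic scoring of classical pain/anxiety assays, fiber-photometry
trace analysis, and a shared two-group testing policy — plus seeded
synthetic generators for all input kinds so that every stage can be
validated against known ground truth. This vignette records the models,
the assumptions behind them, and the design decisions taken where the
methodology is genuinely open.

## Forward-model activation mapping

### The model

Each animal contributes a vector of FOS-positive cell counts over $M$
named brain regions; animals belong to a control (CON) or model (MA)
group. Counts are standardized per region to z-scores (mean 0, sample SD
with denominator $N-1$, both groups pooled), and a soft-margin linear
support vector classifier is fitted to the standardized matrix, giving a
weight vector $W \in \mathbb{R}^{M\times K}$ (for two classes, $K = 1$).

Classifier weights are a *backward* model: a region can receive a large
weight merely to cancel correlated noise, so $W$ itself is not
interpretable region-wise. The package therefore re-expresses the
classifier in the *forward* direction. With data covariance $\Sigma_x$
and latent-score covariance
$\Sigma_{\hat s} = W^\top \Sigma_x W$, the activation pattern is

$$A = \Sigma_x\, W\, \Sigma_{\hat s}^{-1},$$

so that $x \approx A \hat s + \varepsilon$: large $|A_m|$ marks regions
whose measured signal actually carries the group difference, with
positive entries meaning higher standardized FOS in the MA class (the
classifier's sign is canonicalized to point toward the second group
level before the transform).

### Pattern scaling

$A$ as written is the pattern for the *raw* latent score. If $W$ is
rescaled by $c$, $\Sigma_{\hat s}$ absorbs $c^2$ and $A$ scales as
$1/c$ — the direction, rankings, and contribution curve are unchanged,
but the magnitude is not intrinsic. `haufe_transform()` therefore also
returns `A_std` $= \Sigma_x W \Sigma_{\hat s}^{-1/2}$, the pattern for a
unit-variance latent score, whose magnitude is invariant to any
rescaling of the weights. All region rankings in the package may use
either scaling interchangeably; the scale-invariance guarantees in the
test suite are asserted on `A_std`.

### Covariance estimation at $N \ll M$

The motivating design has 3 animals per group and 129 regions, so the
sample covariance is far from invertible. `feature_covariance()` shrinks
the sample covariance toward its diagonal,
$\hat\Sigma = (1-s)S + s\,\mathrm{diag}(S)$, with `shrinkage = "auto"`
selecting $s$ by the analytic rule of Schafer and Strimmer (the ratio of
the summed estimation variances of the off-diagonal entries to their
summed squares, clipped to $[0,1]$). This guarantees a positive-definite
$\Sigma_{\hat s}$ for any nonzero $W$; a singular $\Sigma_{\hat s}$
(condition number above $10^{12}$) is an error instructing the user to
increase shrinkage rather than a silent pseudo-inverse. At the 6-animal
design scale the automatic intensity is typically large (0.7–1), which
biases patterns toward the marginal group differences — the appropriate
behavior when correlations simply cannot be estimated from 6
observations.

Two further conventions keep brain-wide tables usable: z-scoring pools
the two groups (a per-group standardization would erase the group
difference being modeled), and zero-variance regions are set to 0 and
flagged rather than erroring.

### Contribution curve and rankings

Regions are ordered by descending $|A_m|$ (ties broken alphabetically by
region name, for determinism) and their $|A_m|$ accumulated as a
fraction of the total, giving the cumulative activation contribution
curve; `threshold_sets` reports how many regions are needed to reach 50%
and 80% of the total contribution. The curve is monotone, ends at 1, and
is invariant to the input ordering of regions.

### Cross-validation caveat

`cross_validate()` offers leave-one-out and stratified k-fold estimates
of held-out accuracy. At cohorts of a few animals per group these
estimates have very large variance, and LOO on *null* data is known to
be pessimistically biased below chance (the held-out animal's group is
underrepresented in training). The package reports CV accuracy as a
descriptive quantity; the test suite asserts only that null accuracy is
never optimistically inflated.

## Computational ethology

Ethograms are ordered sequences of labeled bouts over a 10-action
alphabet (running, trotting, stepping, walking, rearing, hunching, right
turning, curling-up, sniffing, self-grooming).

* **Action proportions** default to time weighting (fraction of session
  time per action); bout weighting (fraction of bouts) is available.
* **Transition matrices** are bout-level: transitions are counted
  between consecutive bouts, *including* self-transitions, which are a
  reported phenotype in pain models (perseveration of grooming or
  curled-up postures). A pseudocount (default 0 for unbiased
  estimation, 0.5 suggested for sparse chains) is added to every cell
  before row normalization; rows with no observations are emitted as
  all-zero and flagged rather than silently uniformized.
* **Hierarchical clustering** of proportion vectors uses Euclidean
  distance with Ward linkage (`ward.D2`), cut at $k = 2$ by default.
* **Embedding**: `embed_and_classify()` runs exact t-SNE (implemented in
  the package; the cohort sizes of a few dozen animals do not need
  Barnes–Hut approximations) on proportion or flattened-transition
  features, then fits a linear SVM *in the 2-D embedding*. The default
  perplexity $\min(5, \lfloor (N-1)/3 \rfloor)$ respects tiny cohorts.
  The reported boundary accuracy is explicitly descriptive: it is
  training accuracy in a nonlinearly embedded space and must not be
  read as an error estimate.
* **Differential actions** runs the shared test selector per action and
  applies Benjamini–Hochberg across the 10-action family.

All analytics are invariant to relabeling of the alphabet up to the
matching permutation of outputs.

## Behavioral assays

* **Von Frey**: the threshold is the smallest filament of the ladder
  (1.65, 2.36, 2.44, 2.83, 3.22, 3.61; 10 trials each) with strictly
  more than 60% positive responses. Animals never reaching criterion are
  *censored above the ladder*: the result carries the ladder maximum as
  a numeric sentinel plus a `"> 3.61"` label, which keeps rank-based
  group statistics valid (censored animals tie at the top). Filament
  specification values are treated as the ordinal scores printed on the
  filaments; no gram-force conversion is applied. Raising any response
  count can only lower (or keep) the threshold — a property the suite
  checks.
* **Open field**: the center zone is a concentric square whose side is
  `center_fraction` (default 0.5, the common convention; the underlying
  tracking-software default is not standardized) of the arena side.
  Time in zone is per-sample; an entry is a strict outside-to-inside
  transition with a start-inside path counting one entry; displacement
  segments are attributed to the zone of their starting sample. No
  hysteresis band is applied by default.
* **Elevated plus maze**: open arms along x, closed arms along y, a
  5 cm center platform; each sample is assigned to exactly one zone
  class and the open/closed/center classes are scored with the same
  rules, so zone times conserve the session duration exactly.

## Photometry and electrophysiology

* **dF/F** uses the isosbestic control: the 410 nm channel is fitted to
  the 470 nm channel by ordinary least squares over the whole recording
  and $\Delta F/F = (F_{470} - \mathrm{fit})/\mathrm{fit}$. The affine
  fit absorbs shared bleaching and motion artifacts and makes the
  measure invariant to common gain. A constant control channel falls
  back to a 10th-percentile baseline $F_0$ with a warning.
* **Peri-event analysis** aligns windows (default 2 s pre, 5 s post) at
  event times, subtracts each trial's pre-window mean (making the null
  case exactly zero), and drops trials that extend beyond the recording
  with a logged count.
* **AUC** is the trapezoidal integral of the baseline-subtracted trace
  over a configurable window, default $(0, \text{post}]$; it is linear
  in the trace and additive over adjacent windows.
* **Paired-pulse ratio** is peak2/peak1 on amplitude magnitudes;
  rectification of inward currents happens upstream at acquisition.

## Statistics policy

`auto_two_group_test()` mirrors the assay-wide convention: Shapiro–Wilk
on each sample and Levene's test (center = mean) for variance
homogeneity, both gated at 0.05 (the gate itself is a documented
default). Both normal and homoscedastic: pooled t; normal but
heteroscedastic: Welch t; otherwise Wilcoxon rank-sum. Samples with
$n<3$ or zero variance take the nonparametric branch. For two groups,
Levene's statistic is computed as the pooled t test on absolute
deviations from the group means, which is algebraically identical to the
one-way-F form. Family-wise adjustment uses Benjamini–Hochberg.

## Synthetic data: what it emulates and what it does not

Every generator serializes its ground truth next to the data, so
recovery tests never re-derive it.

* **Region counts**: negative binomial per region
  (variance $= \mu + \phi\mu^2$), defaults $\mu = 100$, $\phi = 0.05$,
  two groups, with a multiplicative effect $e^{\beta}$ planted in chosen
  regions. The per-region count magnitudes of real whole-brain data are
  not published at usable resolution, so the defaults are free
  parameters chosen as plausible for regional immediate-early-gene
  counts — recovery tests are about *relative* group structure, which
  the generator controls exactly.
* **Ethograms**: bout-level Markov chains with exponential bout
  durations (mean 2 s) truncated at the session end (default 10 min).
  Real bout durations are not exponential and real sequences are not
  first-order Markov; the generator matches exactly the statistics the
  analytics estimate, which is what makes it a valid oracle and no
  more.
* **Trajectories**: a reflected random walk with a center-avoidance
  drift away from the arena center; step length `speed_scale`/rate.
  This is a minimal model exposing one tunable occupancy parameter, not
  a model of rodent locomotion.
* **Photometry**: shared baseline (100), linear drift and Gaussian
  noise on both channels, plus exponential transients (amplitude in
  dF/F units, $\tau = 1.5$ s) on the 470 nm channel only.
* **Von Frey**: binomial counts under a logistic psychometric function
  of the filament value.

Passing recovery tests on these generators demonstrates that the
estimators invert their own generative assumptions at the stated sample
sizes; it does not certify performance on real tracking noise,
non-Markov behavior, or real FOS count distributions.

## Validation scales and numerical choices

The test suite and the acceptance script validate at the study's design
scales: 6 animals x 129 regions for the covariance/shrinkage path
(with 20/group used for planted-effect recovery so that recovery is a
property of the method, not of luck), 17 ethograms of 10 minutes for
the behavioral pipeline, $10^5$ bouts for transition-matrix round
trips, and 1000-replicate Monte-Carlo loops for type-I/FDR calibration.
Key numerical conventions: sample SD uses $N-1$; the forward transform
refuses condition numbers above $10^{12}$; ranking ties break
alphabetically; row-stochasticity and proportion sums are enforced to
$10^{-9}$; all generators are bit-reproducible given `seed`.

## Known limitations

* $K > 1$ (multi-class) patterns are supported by the linear algebra
  but not by the fitting front end, which is two-group by design.
* The SVM cost parameter defaults to 1 and is not tuned internally;
  with 6-animal cohorts any internal tuning would be noise.
* Repeated-measures designs (longitudinal assay timelines) are out of
  scope; the package compares groups at a time point.
* `run_pipeline()` orchestrates the synthetic end-to-end path and the
  activation/ethology consumers; it is a reproducibility harness, not a
  general workflow engine.
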