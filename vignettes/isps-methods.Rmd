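---
title: "Inter-subject phase synchronization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject phase synchronization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isps)
```

## The model

Conventional GLM analysis of task fMRI is hypothesis-driven: it regresses
each voxel's BOLD amplitude on a reference function built from the task
timing and an assumed hemodynamic response. Inter-subject phase
synchronization (ISPS) instead exploits the fact that every participant
saw the same stimulus sequence: wherever a brain region responds to the
task in a temporally consistent way, the *instantaneous phases* of the
participants' band-limited BOLD signals align. ISPS needs no reference
function to detect task-responsive tissue, makes no assumption about the
shape of the response, and produces a dynamic (per-TR) measure.

For subject $s$ and voxel $v$, the prepared signal $x_{sv}(t)$ is lifted
to its analytic representation $x + i\,H[x]$ (discrete Hilbert transform
via the FFT half-spectrum construction) with instantaneous phase
$\theta_{sv}(t) \in (-\pi, \pi]$. The group synchronization is the mean
resultant length of the $N$ subject phases,

$$ R_v(t) = \Bigl| \tfrac1N \sum_{s=1}^{N} e^{i\theta_{sv}(t)} \Bigr|, $$

i.e. one minus the circular variance: 1 when all phases coincide, 0 when
they cancel. A useful identity links this single group statistic to the
older pairwise formulation: $R^2 = \tfrac1N + \tfrac{N-1}{N}\,
\overline{\cos(\theta_s - \theta_{s'})}$, the mean running over ordered
subject pairs. The package keeps the pairwise form purely as an
independent test oracle (`pairwise_sync_oracle`) and uses the resultant
length everywhere else; the identity is verified to $10^{-10}$ on random
phase sets in the test suite.

The voxels × time matrix of $R$ values is then decomposed with *spatial*
ICA: time points are treated as mixture channels, voxels as samples,
so the sources are spatially independent maps and the mixing columns are
component time courses. Here a component time course is not a BOLD
amplitude — it is the degree of synchronized activity across all
participants attributed to that network at each TR.

## Signal preparation

Per subject and voxel, in this order: discard the first `n_trim_volumes`
(default 10) equilibration volumes; remove a least-squares linear trend;
band-pass to `low_hz`–`high_hz` (default 0.01–0.1 Hz, the conventional
slow BOLD band) with an ideal frequency-domain mask; z-transform with the
population denominator. The order detrend-then-filter is fixed; whether
one z-transforms before or after filtering only changes a per-voxel
scale factor, which phase analysis ignores.

Two numerical choices deserve a note:

* **The filter is an ideal rectangular mask** on the DFT spectrum
  (zero-phase, DC always removed). A zero-phase Butterworth backend
  (`bandpass_butterworth`) is available for users who prefer smooth
  roll-off; the ideal mask is the default because it is the common
  default of resting-state preprocessing toolboxes and is exactly
  idempotent.
* **Preparation is an exact projection.** Detrending and band-passing are
  both orthogonal projections, but they do not commute, so their naive
  composition is not idempotent (re-running it changes values at the
  $10^{-1}$ level). `prepare_series` therefore projects out the in-band
  image of the trend basis after filtering; the prepared series is then
  strictly in-band *and* orthogonal to $[1, t]$, and re-preparing it is
  an identity to machine precision. This matters for reproducibility
  audits where prepared data may be run through the pipeline again.

Voxels with zero variance after filtering (dead voxels, mask edge
artifacts) are dropped from the *common* mask across subjects, so every
subject contributes every analyzed voxel.

Hilbert edge effects: all time points are kept. The analytic signal is
distorted over roughly the first and last few volumes at band-edge
frequencies; tests of phase-increment accuracy therefore exclude a
40-sample margin. Downstream correlations use full-length series to keep
the time-point count at its nominal value (208 in the default paradigm).

## The task paradigm and reference functions

The default design models a blocked pain-empathy paradigm: 16 picture
blocks of 16 s — 4 each of physical pain, affective pain, physical
control, affective control — separated by jittered rest gaps of 8, 10 or
12 s (five of each), with a 20 s lead-in and 10 s tail: 436 s at TR 2 s,
218 acquired volumes, 208 analyzed. The published order of blocks and
gaps is not available, so the package ships one fixed pseudorandom order
(and accepts any order via the BIDS-style events reader; every statistic
is order-agnostic given the design object). The 20 s lead-in equals the
10 trimmed volumes, so the first block onset is 0 s into analyzed time.

Reference functions are boxcars convolved with an HRF kernel on a grid of
10 samples per TR (0.2 s, ample for sub-second onset fidelity), sampled
at volume times, then truncated to the analyzed volumes with onsets
shifted accordingly. Two kernels are provided:

* `gamma_no_undershoot` — a single gamma density with mean lag 6 s and
  width (sd) 3 s, the common default of the FSL family; used for
  synchronization reference functions, because a synchronization time
  course has no post-stimulus undershoot;
* `double_gamma` — the canonical difference of gammas (peak 6 s,
  undershoot 16 s, ratio 6); used by the GLM baseline.

Both are normalised to unit sum so convolution preserves a sustained
plateau's level. The eight association conditions default to the four
single conditions plus the physical/affective/pain/control unions; the
Bonferroni count is `8 × retained components` unless overridden.

## Spatial ICA and model-order selection

The estimator is the fixed-point negentropy ICA with tanh contrast and
symmetric decorrelation, preceded by PCA whitening to the requested
order; initialisation is a seeded random orthogonal matrix, so results
are deterministic given the seed. Components are empirically z-scored and
sign-flipped to nonnegative skewness, so maps read as clusters of *high*
synchronization; thresholding uses z > 2.3 by default.

Convergence warrants honesty: in an exactly Gaussian subspace the tanh
fixed-point update is identically zero in expectation (Stein's identity),
so the rotation there is driven by sampling noise and never settles. This
is the situation in (a) the isotropic noise floor beyond the true signal
rank when the requested order exceeds the number of genuine sources, and
(b) decompositions of pure-noise data, which the split-half null
deliberately exercises. `sync_ica` therefore returns the final iterate
with a warning (and `converged = FALSE`) by default rather than failing;
strict behavior is available via `nonconvergence = "error"`. Non-Gaussian
sources stabilise long before the iteration cap, and planted-network
recovery is unaffected by wandering noise components. A requested order
above the matrix rank is reduced to the rank with a warning, since
synthetic fixtures are often low-rank.

Model order is chosen by split-half replicability: subjects are halved at
random (`n_splits` times, default 10; the larger half takes any odd
subject), each half's synchronization map is decomposed at each candidate
order, components are matched one-to-one across halves by maximum-weight
bipartite assignment on absolute spatial correlation, and the order with
the highest mean matched $|r|$ wins. The metric is one defensible choice
among several — no standard definition exists — and is labelled as such.
Both halves use the same ICA initialisation seed, so feeding identical
half data is a true positive control (replicability exactly 1), while
independent noise scores near zero. Components are flagged `unclassified`
when more than half of their suprathreshold voxels fall in white matter,
CSF or brain-edge territory (the 50% cut is a configurable
operationalisation of the usual qualitative rule), or when the
suprathreshold mask is empty.

## Association statistics

Component–reference coupling is the Pearson correlation over the
analyzed volumes, with a two-sided p from the t distribution on $n-2$
degrees of freedom and Bonferroni adjustment. Condition specificity uses
the independent-samples Fisher z-test
$Z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)/\sqrt{1/(n_1-3) +
1/(n_2-3)}$ with effect size $q = |\mathrm{atanh}\,r_1 -
\mathrm{atanh}\,r_2|$. The independent form is the default because it
reproduces published contrast statistics of this kind at $n = 208$ to
within rounding of the input correlations; a dependent-correlations
(shared-variable) variant is provided (`compare_correlations_dependent`)
for users who prefer to account for the common time course, but it is not
the default. All p-values are two-sided.

Note a calibration caveat: the t-based p-value for a correlation is exact
when at least one series is white. Synchronization time courses are
band-limited and hence autocorrelated, so *absolute* p-values against a
smooth reference are optimistic; the package follows the field's practice
and reports them as nominal, while the test suite calibrates the test
under its white-noise null (rejection rate 0.05 ± 0.015 over 2,000
draws). Users who need exact time-series inference should prefer
circular-shift nulls, which are out of scope here.

## The synthetic generator

`synthetic_spec`/`simulate_group` produce multi-subject 4D series with

* planted networks: voxel masks driven by HRF-convolved boxcars of their
  condition set, amplitude $a_k$;
* per-subject heterogeneity: a response-latency shift $\delta_{sk} \sim
  N(0, \sigma_\ell^2)$ applied to the network's block onsets and a
  multiplicative amplitude factor $1 + \eta_s$, $\eta_s \sim N(0,
  \sigma_a^2)$, both fixed per subject by the seed;
* AR(1) Gaussian noise per voxel (default coefficient 0.3, a mild
  fMRI-like autocorrelation) with marginal sd `noise_sd`, independent
  across voxels and subjects.

Latency draws are stored standardized and scaled by $\sigma_\ell$, so
ensembles at different jitter levels share the same underlying draws —
raising the jitter strictly widens every subject's realised shift, which
makes jitter sweeps smooth rather than re-randomised. The generator uses
the same gamma HRF family as the analysis reference functions; the GLM
baseline still fits double-gamma regressors, whose correlation with the
gamma response is high enough (~0.97) that amplitude detection is
unimpaired. Signals sit on a zero baseline and are written unscaled
(z-scoring happens in preparation).

The desk-scale study configuration — the default arguments — is a 12³
grid, 24 subjects, 218 volumes and three disjoint 3³ networks
(physical-pain, affective-pain, physical-control) at amplitude 1 against
noise sd 1: a full pipeline run takes well under a minute, and the
acceptance script's complete sweep (five simulated groups, four ICA
decompositions, a GLM and a replicability analysis) about one minute on
one CPU. These sizes were chosen so that the whole evidence chain can be
recomputed routinely.

What the generator does *not* emulate: physiological noise and motion,
spatial autocorrelation and anatomy, susceptibility artifacts, and
response-shape variability beyond latency/amplitude. Passing recovery
tests on this fixture therefore demonstrates the correctness of the
method's computations and its qualitative sensitivity profile, not its
performance on real tissue.

### What latency jitter can and cannot show

A per-subject latency shift of sd $\sigma_\ell$ attenuates signal content
at frequency $f$ by $\exp(-(2\pi f)^2 \sigma_{\Delta}^2/2)$ (with
$\sigma_\Delta = \sqrt2\,\sigma_\ell$ for a subject pair). The energy of
a blocked design's condition-locked response lives at roughly
0.01–0.06 Hz, where shifts of a few seconds leave this factor near 1:
in-mask synchronization falls *monotonically* with jitter, and the
component–reference correlation is measurably attenuated, but shifts must
grow commensurate with the 16 s block length (≈ 16 s sd) before the
association actually loses Bonferroni significance. In other words, with
this generator the GLM-positive/ISPS-attenuated dissociation is a
directional effect at moderate jitter and becomes a full ISPS null only
under latency heterogeneity comparable to the block duration — a
consequence of the narrow analysis band, not of implementation. Real
inter-individual variability (different response shapes, signs and
per-event timing) plausibly destroys phase alignment far more efficiently
than a pure constant-latency model.

## Degenerate inputs, ties and tolerances

* Phases are wrapped to $(-\pi, \pi]$; an all-zero series has no phase
  and errors, as does a series whose mean exceeds $10^{-6}$ of its
  amplitude (preparation guarantees zero mean).
* Synchronization values are clamped to $[0, 1]$ against floating-point
  overshoot of the resultant length.
* Zero-variance rows: error in `zscore_rows`, mask exclusion in
  `prepare_group`, error in correlation routines, `NA` + flag in the
  group t-test.
* The split-half matcher adds $10^{-9}$ to all weights so zero-correlation
  edges remain matchable; ties in `which.max`-style selections resolve to
  the first index, and component sign/order have no effect on any
  downstream statistic (tested).
* Bonferroni never lowers a p-value and caps at 1.

## Known limitations

Single-band synchronization only (no wavelet/frequency-resolved variant);
no sliding-window or leave-one-out ISC; no spatial preprocessing (inputs
must be aligned and resampled upstream); no random-field or permutation
correction for maps — the GLM group map is reported unthresholded; and
the association p-values are nominal under autocorrelation, as discussed
above. The atlas-overlap report requires pre-aligned integer labels and
does no resampling.
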