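---
title: "Models and methods behind wmdynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmdynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmdynamics)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, the tunable parameters that matter, and the design
choices made where the design was genuinely open. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## The problem

In a blocked working-memory-manipulation task (mental rotation), behavior
degrades smoothly with difficulty, but success or failure on hard trials is
not explained by *how much* BOLD activity regions produce — the interesting
differences are in *when* regions are recruited. The pipeline therefore
estimates time-resolved regional responses (FIR deconvolution), finds the
low-dimensional axes that separate difficulty levels and performance
outcomes, selects regions by their position on those axes, and then
analyzes timing (cross-correlation) and temporal concentration (energy
landscape) within the selected set.

## Synthetic world

`generator_params()` encodes the emulated design: 24 participants, 2 days ×
8 scans, one 35 s block per scan (5 s instruction; 9 trials of 3 s with a
0.33 s inter-trial interval; 3 trials per difficulty level, order seeded
and shared across participants), TR = 1 s, 482 regions.

Generative behavior is linear in the ordinal difficulty level `d ∈ {0,1,2}`:

- `P(correct) = 0.95 − 0.09 d` — a linear-probability model, so the fitted
  coefficient is directly a per-level percentage-point change;
- `RT = 1.0 + 0.26 d + ε`, `ε ~ N(0, 0.3²)` truncated to `(0, 3]` s.

The accuracy base 0.95 reflects a highly trained cohort (training to ≥85%
before scanning, easiest condition near ceiling); the decrement 0.09 and RT
slope 0.26 s are the calibration targets of the pipeline's recovery tests.
The RT noise SD of 0.3 s is a typical trial-level spread for speeded
responses of ~1–1.8 s. These defaults are fixed once; recovery tests then
treat them as unknowns.

BOLD is generated per run as `Y = S K + E`: `S` holds per-trial impulses at
the trial-onset frame of every responsive region with amplitude
`sign · (1 + gain · d)`, `K` is the causal convolution operator of the
canonical HRF (peak-normalized double-gamma), and `E` is i.i.d.
`N(0, 0.5²)` noise — a 2:1 peak signal-to-noise ratio per frame for a
unit-amplitude response, which is optimistic for single-voxel fMRI but
reasonable for parcel-average time series. Baseline is zero since every
downstream stage z-scores or regresses. On incorrect trials, a designated
subset of responsive regions has its impulse shifted 3 s later — delayed
(not absent) responses are the minimal mechanism that separates correct
from incorrect trials by timing rather than amplitude.

**Region roles and why gains must vary.** `region_roles()` assigns
difficulty-*gain* regions (gain 0.5), difficulty-flat responsive regions
(gain 0), and negative regions. The heterogeneity is not cosmetic: the
latent-axis stage z-scores across regions at each timepoint, and a
difficulty gain shared by *all* responsive regions is a common scale factor
that cancels under that normalization — the difficulty axis would then
carry almost no regional information. With heterogeneous gains, increasing
difficulty tilts the spatial pattern toward the gain regions and the axis
becomes identifiable. Of the 482 default regions, 60 are gain regions (the
first 30 also delayed on errors — the ground-truth "hard and correct" set),
40 are flat, 20 negative, the rest unresponsive noise.

What the generator does *not* emulate: voxel-level structure, motion and
physiological artifacts, scanner drift, autocorrelated noise, spatially
correlated noise, variable HRFs, and between-participant heterogeneity of
effect topography. A green test therefore establishes that the *estimators*
recover a stated generative structure — not that the real data satisfies
that structure.

## FIR window and design

`response_window()` derives the window length from first principles:
convolve a boxcar of the trial duration with the canonical HRF sampled at
TR and return the number of frames up to the first strictly negative
sample. With SPM-convention parameters (peak 6 s, undershoot 16 s,
dispersions 1, ratio 6) and a 3 s trial this gives a first negative at 14 s
and a 15-frame window. The convolution is computed by exact cumulative
sums: an FFT-based convolution turns the exact zero of the HRF at t = 0
into a ~−1e−17 value, which would falsely trigger "first strictly
negative".

`build_fir_design()` lays one indicator column per (condition, timepoint
offset); trials of a condition share columns, so betas are the condition's
mean trial-locked response. Nuisance: one day regressor plus one indicator
per scan — 15 + 1 + 16 = 32 columns for the single-condition
(hard-incorrect) design over 2 days × 8 scans; 62 for the three-difficulty
design. The day column equals the sum of its scans' indicators, so the
nuisance block is collinear by construction; the pivoted QR drops a
redundant nuisance column, which provably leaves the FIR betas unchanged
(the FIR columns are outside the nuisance span). An aliased *FIR* column is
a genuine identifiability failure and errors.

**Onset rounding.** The design's inter-trial spacing (3.33 s) is not a
multiple of TR, so onsets cannot sit exactly on the frame grid. Default
behavior rounds onsets to the nearest frame, the standard FIR practice;
`onset_rounding = "strict"` errors on off-grid onsets for grid-aligned
designs. The generator places its injected responses with the same
rounding, so the two stages agree exactly.

**Joint versus separate condition models.** With trials 3.33 s apart and a
15 s window, responses of neighboring trials overlap heavily. Least squares
unmixes overlap only for *modeled* events: a single-condition model that
leaves ~90% of the surrounding trials unmodeled acquires a systematic,
shared bias in its betas (in noiseless simulation it shifts the detected
hard-incorrect delay from the injected 3 s to 4 s). `fit_study_fir()`
therefore defaults to a joint four-condition design (easy/medium/
hard-correct + hard-incorrect; all trials modeled; noiseless recovery is
then exact up to the response tail, see below), and offers
`model = "separate"` for the two-model scheme in which the difficulty model
uses only correct trials and a separate 32-regressor model fits
hard-incorrect responses. The design-bookkeeping contracts (32 and 45 FIR
columns) are unaffected.

**Response tails.** The canonical HRF has support to ~32 s; a 15-frame FIR
window cannot represent the small undershoot tail beyond 14 s, which leaks
into the scan-intercept estimate. Exact-recovery tests therefore inject a
window-limited kernel; with the full kernel the residual bias is a fraction
of the undershoot amplitude and does not move integer lag estimates.

**Mixed-model contract.** The per-participant GLM treats day as fixed and
scan as a random intercept in the reference analysis. The default fitter
uses fixed scan intercepts (one OLS solve for all regions); the
`method = "mixed"` route fits lme4 per region and falls back to the fixed
fit on convergence failure with a warning. On balanced noiseless data the
two agree, which is asserted in the tests.

## Latent axes

Z-scoring is per (participant, condition, timepoint) across regions,
pooling nothing: each spatial pattern is normalized to mean 0, SD 1. PCA
stacks those patterns as rows (participant × condition × timepoint) over
region columns — the only stacking that yields PC *spatial maps* over
regions while allowing per-timepoint classification — and centers columns.

The sweep trains a Fisher discriminant on the first k PC scores of the
observations at timepoint t, for t = 1…15 and k = 1…40, scoring out-of-fold
balanced accuracy (mean of sensitivity and specificity; chance 0.5) under
5-fold cross-validation whose folds never split a participant. The
operating point takes the timepoint attaining the grid maximum (ties →
earliest timepoint) and the minimum PC count achieving it there. On clean
synthetic data large parts of the grid saturate at 1.0 and the tie rule
selects early timepoints; this is the stated selection rule, not a defect,
and the final axes are trained at the selected timepoint with a fixed
default of 13 PCs (`select_n_pcs_variance()` implements the ">1% added
variance" alternative).

**Shrinkage.** With ~24 observations per class in 13 dimensions the pooled
within-class covariance is ill-conditioned, and the raw Fisher direction —
though an excellent classifier — is a noisy *map*: its inverse-covariance
rotation amplifies sampling error in exactly the way that corrupts region
loadings. `fisher_lda()` therefore shrinks the covariance toward a scaled
identity with the Ledoit–Wolf intensity by default (`shrinkage = "auto"`,
the standard small-sample choice; the used intensity is logged in the
returned axis). `shrinkage = 0` recovers the textbook Fisher discriminant,
which the tests check against the closed form Σ⁻¹(μ₂ − μ₁) on spherical
Gaussian classes.

Sign conventions: the second factor level of the label vector projects
positively; both axes are oriented so hard-correct is positive, making
quadrant 1 well-defined. Gram–Schmidt normalizes axis 1 and replaces axis 2
by its normalized residual; the |r| between each orthogonalized axis and
its raw axis is reported (computed between the axis coordinate vectors in
PC space — the alternative, correlating region loadings, differs only by
the PCA basis change).

## Region selection and net BOLD

Quadrants follow the task semantics (difficulty loading positive = hard;
performance loading positive = correct): Q1 hard-correct, Q2 easy-correct,
Q3 easy-incorrect, Q4 hard-incorrect. Zero loadings (measure-zero) resolve
deterministically to the positive side.

Net BOLD is the signed rectangle-rule area `Σ_t β_t · TR` — pointwise
accumulation over all timepoints, positive and negative excursions
canceling. The rectangle rule is chosen over the trapezoid because the
statistic is defined as accumulation "across all timepoints"; the two
differ only by a boundary term. The per-region difficulty effect models
net BOLD on ordinal difficulty with a random participant intercept
(`method = "mixed"`; fixed participant intercepts as fallback), two-sided
p from the t distribution with residual degrees of freedom (the
environment provides no Satterthwaite approximation; with 24 × 3
observations per region the difference is negligible), and
Benjamini–Hochberg q across regions at Q < 0.05.

## Temporal dynamics

Cross-correlation uses Pearson correlation of overlapping segments at each
integer lag (per-lag normalization, no zero padding), lags −7…7 so every
overlap keeps ≥ 8 points of a 15-point series. A positive lag means the
second series trails the first. The peak lag is the argmax over valid
lags; ties break toward the smallest |lag|, then the positive sign.
"Delayed" means peak lag ≥ 1 frame with positive peak correlation — the
delay magnitude is reported, the flag is threshold-based.

The energy landscape pools |beta| samples across the selected regions and
participants per timepoint (a per-participant option exists via direct
calls with subset matrices) and evaluates the Gaussian-kernel density
`P(x) = (1/hn) Σ_i K((x − x_i)/h)` with h = 0.1 on a grid over [0, 1.8]
(step 0.01; both bounds configurable since nothing intrinsic fixes 1.8),
then `E = −ln P`, with `P = 0` cells carrying `Inf`. The estimator is the
standard KDE form — the evaluation point belongs inside the kernel
argument; a kernel evaluated at the samples alone would not define a
density over the grid.

## Behavior models

Trial-level accuracy uses an identity-link (linear-probability) mixed model
by default so the difficulty coefficient is directly a per-level
percentage-point change; `family = "logistic"` is available. RT models use
correct trials only (errors may reflect non-task processes); the exclusion
is asserted by sample-size contract in the tests. Random structure is scan
nested in participant, simplified to participant-only and then to fixed
intercepts on convergence failure, each simplification logged. Confidence
intervals use the t distribution with `nobs − n_fixed` degrees of freedom.

## Numerical choices and degenerate inputs

- Boxcar convolution by cumulative sums (exact; no FFT round-off).
- Onsets rounded to the nearest frame; `"strict"` mode errors beyond 1e−6 s.
- Z-scoring errors on zero-spread slices, naming the slice.
- PCA truncates `n_max` to the numerical rank with a warning.
- Sweep cells whose training folds lose a class are NA (invalid), never 0.
- Collinear axes (residual < 1e−10 of the norm) error in Gram–Schmidt.
- Zero-variance cross-correlation overlaps are NA per lag; an all-NA
  correlogram errors.
- Seeds: all generator randomness derives from `params$seed` (schedule:
  seed; behavior: seed + 1; BOLD noise: seed + 2) under a temporary RNG
  state, so identical parameters give bit-identical outputs and the
  caller's RNG is untouched.

## Known limitations

- The generator's noise is white; FIR standard errors on real,
  autocorrelated BOLD would be optimistic (no prewhitening is
  implemented).
- The sweep grid on clean synthetic data saturates, so operating points
  degenerate to the tie rule; on real data the grid is informative.
- p-values from mixed fits use residual-df t approximations rather than
  Satterthwaite/Kenward–Roger corrections.
- The delayed/not-delayed flag uses a 1-frame threshold; sub-TR delays are
  out of scope (no interpolation).
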