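---
title: "Methods: models, estimators and design choices in gecibench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in gecibench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

gecibench quantifies the performance of genetically encoded calcium
indicators (GECIs) from fluorescence time series, and ships a
spike-to-fluorescence forward model so that every estimator in the pipeline
can be validated by parameter recovery against known ground truth. This
vignette explains the models, the estimators, the tunable parameters, and
the design decisions that were genuinely open.

## The forward model

### Transient kernel

A burst of action potentials produces a fluorescence transient modeled as a
difference of exponentials,

    h(t) = (1 - exp(-t / tau_r)) * exp(-t / tau_d),   t >= 0,

scaled so that the burst's peak dF/F0 equals the indicator's amplitude curve
at the burst's AP count. Indicator kinetics are published as half-rise and
half-decay times, not time constants, so `solve_kernel_taus()` inverts the
kernel's half-time equations numerically (nested root bracketing inside a
Nelder-Mead solve on log time constants, relative tolerance 1e-5).

Two anchoring conventions exist because published half-decay numbers come
from two kinds of measurement:

* `decay_anchor = "burst"` (in vivo and culture presets): the preset
  half-decay is the kernel's own peak-to-half time. This matches estimates
  taken from isolated transients.
* `decay_anchor = "tail"` (NMJ presets): the preset half-decay is the
  half-time of the exponential tail after a stimulus train,
  `tau_d * ln 2`. Published NMJ decay times were measured after 2 s tetanic
  stimulation, where the superposed response decays as a near-pure
  exponential in `tau_d`; anchoring the kernel's single-burst half-decay
  instead would make the model's post-tetanus decay systematically faster
  than the number it claims to embody.

### Burst grouping and saturation

Calcium (and hence dF/F0) does not summate linearly over rapid spiking; the
model therefore applies a saturating amplitude curve per burst rather than
summing single-AP kernels. Spikes are grouped into bursts by chaining:
consecutive spikes separated by at most `burst_window_s` (default 0.25 s,
the widest AP-binning window used in the fast-indicator detection analysis)
share a burst. Chaining, rather than a window anchored at the first spike,
makes a contiguous 83 Hz or 160 Hz train a single burst, so that a 160-AP
train saturates at `amplitude_curve(160)` rather than at the sum of several
fragment bursts. Bursts separated by more than the window superpose
additively, which is exact for inter-burst intervals of a few decay times.

### Amplitude curve

Only a handful of per-AP amplitudes are published (for example the NMJ
single-AP dF/F0 of 11.6%, 8.6% and 4.5% for jRGECO1a, jRCaMP1a and GCaMP6s).
Interior values of the amplitude curve use the saturating per-AP increment

    A(n) = A_max * (1 - (1 - A_1 / A_max)^n),

which equals the single-AP amplitude at n = 1, is nondecreasing, and
saturates at the indicator's dynamic-range ceiling `amp_max`. Every preset
records which fields are published values and which are estimates
(`anchored`); in vivo single-AP amplitudes are not published and are
explicitly unanchored estimates. No acceptance-grade check depends on
unanchored values.

### Imaging model

`render_fov()` produces the two channels the correction stage consumes:

* neuropil channel: `F_np = f0 * (1 + fluct)`, where `fluct` is a smooth
  zero-mean Gaussian process (white noise convolved with a 1 s-sd Gaussian)
  scaled to sd `neuropil_amp`. The 1 s correlation length makes the shared
  contamination slow relative to the transients, which is the regime the
  scaled-subtraction correction assumes.
* true cell signal: `f0 * (1 + dff)` plus additive white Gaussian noise of
  sd `noise_sd * f0`. Noise is additive on raw fluorescence, not on dF/F0;
  a shot-noise option is deliberately not modeled.
* measured cell signal: `F_meas = F_true + r_true * F_np`.

With noise off the chain `render_fov -> neuropil_correct(r = r_true) ->
compute_f0 -> compute_dff` reproduces the input dF/F0 to better than 1e-9,
which the test suite asserts.

### Stimulus-driven population

`generate_tuned_population()` emulates the visual-cortex protocol: 8
drifting-grating directions separated by 45 degrees, 5 trials per direction,
each trial 4 s blank followed by 4 s stimulus. Responsive cells fire
inhomogeneous-Poisson spikes at a double-Gaussian direction-tuning rate
(defaults: peak rate 8 Hz, opposite-lobe 2 Hz, background 0.3 Hz, width 30
degrees); non-responsive cells fire only background spikes. Defaults were
chosen once as typical layer-2/3 values and are not revisited per analysis.

What the generator does *not* emulate: pixel-level movies and ROI
segmentation, motion artifacts, slow drift and photobleaching, lysosomal
accumulation of indicator, spike-history-dependent amplitudes beyond the
per-burst curve, and hemodynamic or depth-dependent absorption within a
recording. Passing recovery tests therefore demonstrates estimator
correctness under the stated noise model, not robustness to every artifact
of real two-photon data.

## The analysis stages

### Trace correction

`neuropil_correct()` subtracts `r * F_np` elementwise (default r = 0.7).
Cells qualify only when their baseline fluorescence exceeds the neuropil
baseline by more than 3% (`check_eligibility()`); the baseline windows are
the same 1 s pre-stimulus windows used for F0. Whether the 3% rule should
use whole-recording means instead is not specified by its source; the
pre-stimulus choice is exposed through the `baseline_windows` argument.
`moving_average()` (3-point) exists for display only and is never applied
before quantitative estimators.

### Responsiveness and tuning

Per-trial responses are stimulus-period means of dF/F0 with a per-trial F0
from the preceding 1 s of blank. A cell is responsive when its
trial-averaged response exceeds 0.05 for at least one direction *and* a
classical one-way fixed-effects ANOVA across nine groups (blank plus eight
directions) rejects at p < 0.01. The trial structure yields one blank period
per trial (40 in total); these are collapsed to one mean per repetition
cycle so the ANOVA is the balanced 9 x 5 design. The frame-wise alternative
reading of "dF/F0 > 0.05 during at least one stimulus period" was rejected
because frame-wise maxima are noise-dominated at realistic noise levels.

The tuning curve is fitted with a sum of two circular Gaussians of common
width, with the second lobe at `theta_pref + delta`. Stimuli are drift
directions spanning 360 degrees while the orthogonal orientation sits at 90
degrees; whether responses should be folded into orientation space first is
ambiguous, so both `delta = 180` (direction space; the default) and
`delta = 90` (literal orthogonal-orientation placement) are implemented.
Fitting uses multi-start L-BFGS-B (4 deterministic starts, theta at the
preferred stimulus and its neighbor, widths 20-60 degrees) with bounds
sigma in [5, 180] degrees and nonnegative amplitudes. OSI is computed from
the fitted model at the preferred direction and at +90 degrees; it is
invariant under multiplicative scaling of the curve, and undefined (flagged)
when the two responses sum to zero or less.

### Kinetics

Half-rise and half-decay times locate the first crossing of half the
baseline-subtracted peak by linear interpolation between bracketing samples;
on a sampled exponential the half-decay estimate converges to `tau * ln 2`
as the frame rate grows, which the suite checks at 15, 60 and 240 Hz. The
peak is the global maximum of the analysis window. Transients qualify for
decay analysis only when the peak in the last 1 s of stimulation exceeds 4
baseline standard deviations (a zero-variance baseline with any peak above
baseline qualifies, by convention). `fit_exp_decay()` quantifies "small
fitting error" as RMS residual normalized by fitted amplitude, threshold
0.1 by default, since no numeric threshold is published.
`fourier_tracking()` uses a rectangular window without padding and reports
the magnitude at the bin nearest the stimulus frequency, normalized to the
0 Hz magnitude; spectra are computed per cell and then averaged (computing
them on averaged traces instead is a caller-level choice).

### Spike detection

Event extraction clusters spikes by a >1 s isolation gap; an n-spike
cluster becomes an n-AP event when its span fits the per-indicator bin
schedule (100 ms at 2 APs growing by 25 ms per AP for fast indicators;
150 ms growing by 50 ms, capped at 350 ms, for slow ones). Event-local F0
is the mean of the 10 frames before the first AP. Templates are per-class
mean snippets, mean-subtracted and unit-normalized; raw snippets are
projected onto them. Whether all classes should share a single template is
ambiguous; per-class templates are the default and a common-template option
is exposed. d-prime uses equal-weight pooled sample variances. The ROC
threshold rule is "positive when score > threshold" with ties grouped; its
area equals the Mann-Whitney U statistic divided by the product of group
sizes, an identity the suite asserts exactly. `accuracy_at_fpr()` takes the
noise-score order statistic at `ceiling((1 - fpr) * n)` ("higher"
convention) as threshold; convention and tie handling change the result by
O(1/n) and are fixed so results are reproducible.

### Depth attenuation and screen analytics

Depth profiles are fitted per dendrite as `F(z) = F0 exp(-z / lambda)` by
unweighted log-linear least squares (a nonlinear option agrees within 1% on
clean data); slopes indistinguishable from zero are flagged with
`lambda = Inf`. Group summaries report median and sd with a two-sided
Wilcoxon rank-sum comparison.

Screen metrics are computed per cell (the per-well unit of replication is
available by aggregating the returned table); SNR is the fluorescence peak
above baseline divided by the pre-stimulus sd, with a 1 s baseline at the
35 Hz screen frame rate. Variant ranking counts significant amplitude
improvements over the parent at 1, 3 and 10 APs (rank-sum p < 0.01 and
fold > 1), excludes variants with a significant 160-AP reduction, and
breaks ties by mean fold-change.

## Numerical choices and degenerate inputs

* Window ends are exclusive by half a frame, so a sample at exactly the
  stimulus-onset time never leaks into the preceding baseline.
* Ties in the preferred-stimulus argmax go to the lowest direction label.
* `classify_responsive()` on noiseless input with zero within-group variance
  rejects iff the group means differ at all (the F statistic degenerates).
* Empty spike trains render as identically zero traces, not errors.
* `compute_dff()` refuses F0 <= 0: such cells must be excluded upstream by
  the eligibility rule.
* All generators are bitwise-reproducible from the seed in their
  configuration.

## Problem sizes

The test suite runs populations of 12-30 cells at 15 Hz, event sets of
40-120 events, 200-dendrite recovery sweeps, and a 10^4-cell null
calibration of the responsiveness classifier; these sizes give binomial or
Monte-Carlo error well inside the asserted tolerances while keeping the
default run fast. The benchmark script uses the study's own group sizes
where they are published (19 red and 14 green dendrites, 12 NMJ fields of
view).

## Known limitations

* The amplitude curve is a one-parameter saturation model; real indicators
  show supralinearity at low AP counts that it does not capture.
* The neuropil fluctuation is a stationary Gaussian process; real neuropil
  contains stimulus-locked signal, which makes the correction matter more
  in practice than in simulation.
* Poisson spiking ignores refractoriness and bursting statistics.
* The double-Gaussian fit is a least-squares point estimate; no uncertainty
  on OSI is propagated.
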