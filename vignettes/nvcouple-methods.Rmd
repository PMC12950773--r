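---
title: "Methods: odor-evoked neurovascular coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odor-evoked neurovascular coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcouple)
```

## The measurement and its sign conventions

Widefield imaging of the dorsal olfactory bulb (dOB) yields two
trial-structured channels. The blood-volume channel records 590 nm
reflectance — the hemoglobin isosbestic wavelength, so the signal
reports total blood volume rather than oxygenation — at 7 Hz; because an
increase in blood volume increases absorption, **responses are negative
in reflectance dF/F**. The calcium channel records GCaMP6f fluorescence
from mitral/tufted cells at 25 Hz, positive-going. All dF/F values are
percentages relative to the mean over the pre-odor baseline (trial start
to odor onset at 8 s), so each pixel's pre-odor dF/F mean is exactly
zero by construction.

Everywhere a blood-volume trace meets the transfer-function machinery it
is sign-flipped first ("oriented"), so the fitted kernel is
positive-going and its amplitude `y_m` is reported on the oriented
scale. AUC, in contrast, is reported on the as-acquired reflectance
scale (negative = larger response), with `auc_oriented` carried
alongside in the metrics table.

## The transfer-function model

The hemodynamic impulse response is a peak-normalized gamma variate

$$h(t) = y_m\,u^{\alpha} e^{\alpha(1-u)}, \qquad u = \frac{t - y_0}{t_m},
\qquad h(t) = 0 \ \text{for}\ t < y_0 .$$

This parameterization is chosen so the parameter names mean what they
say: `y_m` **is** the peak value and `t_m` **is** the time from the end
of the onset delay `y_0` to the peak (absolute peak time `y_0 + t_m`).
A non-peak-normalized gamma variate would describe the same shape family
but with `y_m`/`t_m` losing those literal meanings; if reference
implementations used such a variant, recovered `y_m` values would
rescale while the shape and goodness of fit are unaffected. Two FWHM
routines are provided: the empirical closed form
$(2.454\,\alpha^{-0.5256})\,t_m$ and an exact bisection solver
(`fwhm_numeric()`). The closed-form constants are a power-law
approximation fitted at small shape values: against the exact width the
relative error is 0.31/0.43/0.03/0.76% at $\alpha$ = 1/2/3/5 and grows
to ~2.1% at $\alpha$ = 10 (asymptotically the true width behaves as
$2.3548\,\alpha^{-1/2} t_m$, so any fixed power law drifts at large
$\alpha$). Both are exposed so users can check the approximation on
their own fits.

Discrete convolution is causal, computed as a running sum multiplied by
the sample interval, and truncated to the input length — so convolved
traces keep units independent of the frame rate.

## Pipeline stages and their numerical choices

**dF/F** (`compute_dff`): per pixel, $100\,(F - F_0)/F_0$ with $F_0$ the
pre-odor mean. Pixels with $F_0 = 0$ are flagged and excluded from all
ROIs. Invariant to global camera gain.

**Drift removal** (`fit_remove_exponential`, `detrend_dff_movie`): LED
dimming and photobleach are modeled as $a e^{-t/\tau} + c$, fitted by
least squares to all samples *outside* the response window (odor onset
to onset + 13 s) and subtracted. The constant added back is the fitted
curve's **pre-odor mean**, which preserves each trace's pre-odor level
exactly; when the drift has decayed by trial end this equals the
asymptote $c$, but for slow drifts adding back $c$ itself would inject
an offset as large as the drift amplitude, which then collides with the
zero padding of the aligned trace. ROI-level traces use a per-trace
Levenberg–Marquardt fit (falling back to a flagged linear detrend if it
fails); the pixel-level version used before ROI thresholding shares one
global $\tau$ (drift is spatially common) chosen on a log grid of 24
values in [2, 100] s, with per-pixel $(a, c)$ solved in closed form.
Pixel-level detrending is on by default in `pixel_response_stats()`
because a drift of a few percent over the 10 s response window otherwise
exceeds the SD thresholds everywhere and makes every pixel "responsive".

**ROI selection** (`pixel_response_stats`, `consistency_mask`,
`rect_mask`): per pixel and trial, the baseline SD of dF/F (pre-odor
frames) and the response metric — by default the *mean* dF/F over onset
to onset + 10 s, matching the AUC window; a peak option exists since the
choice between mean and peak is not dictated by the protocol. A pixel
exceeds at level $k$ when $-\text{response} > k \cdot \text{SD}$
(strict inequality; the minus sign puts the test on the blood-volume-
increase axis). The `SD1` rule requires 4 of 6 trials at 1 SD, `SD3` 3
of 6 at 3 SD, using the 6 trials per concentration pooled across the two
odorants. Hemispheres split at the vertical midline. Empty masks are
returned with a warning flag, not an error — at low concentration an
empty 3 SD mask is the scientifically correct answer. Baseline SD is
per trial, not pooled, for robustness to inter-trial drift.

**Alignment** (`resample_align`): linear-interpolation upsampling of the
BV trace to 25 Hz, 4 s pre / 15 s post onset, then 100 zeros appended —
575 samples with onset at sample 101 (i.e. 100 samples strictly before
onset; serialized 0-based as t0 = 100). Linear interpolation (rather
than Fourier) avoids ringing on the slow hemodynamic signal and keeps
results bit-reproducible. The zeros are appended *after* the 19 s data
window; placing part of the window inside the padding instead would
discard response samples.

**Deconvolution** (`deconvolve_gcamp`): the calcium trace is modeled as
the firing rate convolved with $e^{-t/\tau}$, $\tau$ = 250 ms. The exact
discrete inverse is the causal two-tap filter
$r_i = (c_i - e^{-\Delta t/\tau} c_{i-1})/\Delta t$ — $O(n)$, no edge
artifacts, machine-precision round trip. The indicator *rise* time is
ignored (a documented limitation; only the decay is inverted). Negative
values are clipped in the reported rate (rates are nonnegative) but the
unclipped series is retained and used for the transfer-function fit to
preserve linearity.

**Transfer-function fit** (`fit_transfer_function`): bounded nonlinear
least squares (Levenberg–Marquardt via `minpack.lm::nls.lm`) minimizing
$\sum (\text{rate} * h - \text{BV}_\text{oriented})^2$ from starting
values (0.8, 4, 3, 0.2), function tolerance 1e-10, at most 700
iterations. Bounds — $t_m \in [0.1, 15]$ s, $\alpha \in [0.2, 50]$,
$y_0 \in [0, 5]$ s, $y_m > 0$ — are guardrails against degenerate spikes
on noisy trials; bound hits are flagged in the result. If the fit fails
to converge or the goodness of fit is below 0.5, eight jittered restarts
(fixed internal seed, so results stay deterministic) are tried and the
best kept. The appended zeros participate in the objective, penalizing
non-causal or overshooting tails. Goodness of fit is the maximum
normalized cross-correlation over lags up to ±12 frames (~0.5 s at
25 Hz), with positive lag meaning the prediction is delayed. Fits are
per trial (an averaging switch exists at the pipeline level via
configuration of the inputs); per-trial fitting matches the per-trial
dispersion statistics the metrics stage consumes.

**Metrics** (`auc`, `coupling_ratio`, `concentration_slope`,
`age_regression`): AUC is the plain frame sum of %dF/F over
round(10 s × rate) frames from onset — exactly 70 frames on the native
7 Hz BV trace, which is why AUC is computed before upsampling. The
coupling ratio is BV/Ca on oriented values, undefined below a
denominator floor (1e-9). Concentration-response slopes are ordinary
least squares per subject on the linear %-SVP scale — chosen because
fold changes over the 10-fold 0.3 → 3% span are reported alongside — with
a log10 option, followed by a one-sided one-sample t-test of slopes > 0
across subjects (the degenerate all-equal-slopes case returns the
limiting p of 0.5/0/1 by sign). Age regressions are per genotype, with
the slope reported both raw and as percent of the group-mean |AUC| per
month; the normalization convention is recorded in the output because
percent-AUC-per-month is not otherwise self-defining.

## The synthetic-session generator

`synthesize_session()` is first-class, tested code that defines the
study conditions. Per odorant it emits 3 control trials then 9 odor
trials (3 concentrations × 3 repetitions; EB then MV), so pooling
odorants gives 6 trials per concentration. Inside the per-hemisphere
vessel masks each pixel follows
$\text{baseline}\,(1 + s(t))\,b(t) + \varepsilon$:

- $s(t)$ is the firing rate convolved with the GCaMP6f kernel (calcium,
  positive) or with the true gamma-variate HRF, sign-flipped (blood
  volume, negative). Scale factors are fixed at the highest-
  concentration reference so responses stay exactly linear in the
  firing rate.
- the firing-rate template rises within ~0.5 s of onset, sustains with
  20% adaptation, and returns to zero within 3 s of offset; its peak
  equals the concentration gain (defaults 1 / 1.8 / 3.2 at 0.3/1/3%,
  roughly doubling per concentration decade).
- $b(t) = 1 - A(1 - e^{-t/\tau_b})$ is the multiplicative bleach/LED
  drift (defaults $A$ = 5%, $\tau_b$ = 20 s).
- $\varepsilon$ is white Gaussian noise, SD = 0.2% of baseline per pixel
  per frame (a clean widefield preparation; per-pixel amplitude SNR 10
  at the highest concentration, far higher on ROI-mean traces).

Default peak dF/F are −2% (BV) and +8% (Ca) at 3% — typical widefield
magnitudes, free parameters of the generator rather than claims about
any particular dataset. A4T2 subjects scale response amplitude by
`genotype_gain × (1 + age_gain_per_month (age − 12))` (defaults 1.3 and
0.05/month) while WT amplitudes are age-flat, emulating genotype-
dependent vascular hyperresponsiveness. Vessel masks are branching
random-walk polylines dilated to 2–5 px — sparse, artery-like geometry
for the SD thresholds to find. Vessel geometry derives from a separate
`structure_seed`, so sessions with different noise seeds share identical
ground truth. Trials are generated independently (no baseline
continuity across the 180 s inter-trial intervals, which the analysis
never uses). The default image size is 64 × 64, a desk-scale reduction
of the 256 × 256 acquisition geometry; all code is size-agnostic and
the examples/tests state the sizes they use.

What the generator does *not* emulate — optics/PSF blur, heartbeat and
respiration artifacts, motion, hemispheric asymmetries beyond
independent masks, structured (non-white) noise — bounds what passing
tests show: they validate the estimators against the stated forward
model, not robustness to every artifact of real preparations.

## Identifiability: what the method can and cannot recover

Three properties of the procedure are worth knowing and are quantified
in the test suite:

- **Noiseless trace-level inversion is exact**: when the measured BV is
  the model's own convolution (tail included), all four parameters are
  recovered to optimizer tolerance from the default start and from
  starts ±50% from truth.
- **The zero padding biases long-tailed kernels.** The measured aligned
  trace is zeroed beyond 19 s, but a kernel with $t_m$ = 4, $\alpha$ = 3
  still carries ~8% of peak amplitude there; penalizing the model's tail
  against those zeros inflates recovered $\alpha$ by ~15–20% and $t_m$
  by a few percent end to end. This is a property of the windowing
  design, shared with the procedure being modeled; fit quality is
  unaffected (gof > 0.999 noiseless).
- **The onset delay `y_0` is weakly identified in noise.** At
  amplitude-SNR 20 on a single trace the Cramér–Rao bound already puts
  the delay's standard error at ~0.22 s against a true value of 0.2 s
  ($y_0$ trades off against $t_m$ under a smooth kernel). Estimating
  hemodynamic onset latency to tens of milliseconds from single noisy
  trials is not possible regardless of optimizer; averaging trials or
  fixing `y_0` are the practical remedies.

## Pipeline orchestration

`run_pipeline()` is a pure function of (session directory, config):
masks per concentration, ROI traces, detrending, AUC on the 7 Hz trace,
alignment, deconvolution and per-trial fits, with every artifact written
(TIFF masks + JSON descriptors, CSV traces/fit table/metrics, JSON
summary, markdown report) and warnings (empty masks, fallback detrends,
non-converged fits) collected into the report. Reruns are byte-identical.
Transfer functions are fitted on the `SD1` ROI by default: the 3 SD rule
legitimately selects no pixels at the lowest concentration, and an
analysis that silently loses a concentration level is worse than one
using the less selective ROI; `fit_roi_kind = "SD3"` restores the
artery-like choice where masks exist. Configuration is plain R or YAML
(`pipeline_config(yaml = ...)`), with defaults frozen to the protocol
constants (8 s onset, 4 s odor, 7/25 Hz, 250 ms τ, 10 s AUC window,
13 s detrend exclusion, 4/15 s alignment, 100 zeros, (0.8, 4, 3, 0.2)
start, 1e-10 tolerance, 700 iterations, 1 SD–4/6 and 3 SD–3/6 rules).

## Study sizes used by the shipped checks

The acceptance studies run at desk scale: sessions at 64 × 64 (full
trial counts), 50-replicate noisy-recovery simulations, 8-subject
trace-level cohorts, and 20-trial high-SNR fit-quality studies. These
sizes were chosen so the complete suite runs in minutes on one CPU while
keeping every statistical check comfortably powered.
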