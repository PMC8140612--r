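---
title: "Analysing passive block-design auditory fNIRS: averaging, GLM, and detection"
author: "fnirsblock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing passive block-design auditory fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsblock)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through light attenuation at two wavelengths. In a passive
auditory block design, short stimuli (here: 5.25 s of speech, 5 s of
band-limited noise, 5 s of silence as a control) are presented in random
order with 10–20 s of silence between them, and the question is whether
and how strongly auditory cortex responded. Two analysis families
dominate: **epoch averaging**, which cuts and averages the signal around
stimulus onsets, and the **general linear model (GLM)**, which fits a
model response to the entire recording. This package implements both
routes end to end, the short-channel systemic corrections that matter at
the single-subject level, an ROC framework for quantifying detection
performance with the silent condition as the false-positive probe, and
mixed-effects group inference — together with a forward simulator that
generates raw-intensity recordings with known ground truth, so that every
claim the pipelines make can be checked against a simulated truth.

## The measurement model

A channel is a source–detector pair. Long channels (20–40 mm separation)
see cortex plus superficial physiology; short channels (< 10 mm) see only
the superficial, systemic component. The montage here has 12 sources, 12
detectors and 8 short-channel detectors: 24 long channels grouped into
four regions of interest (left inferior frontal gyrus, left and right
superior temporal gyrus — the auditory ROIs — and an occipital control
region), plus 8 short channels. Optode positions come from a standard
10-05 coordinate table; on the nominal head all long separations fall
between 29 and 40 mm, and a global head-scale factor is exposed for other
head sizes. The 8 mm short-channel offset is hardware-fixed and does not
scale.

The forward optics follow the modified Beer–Lambert law. Concentration
changes $\Delta c = (\Delta\mathrm{HbO}, \Delta\mathrm{HbR})$ in µM map
to optical density at wavelength $\lambda$ as

$$\Delta OD_\lambda(t) = d\,\mathrm{ppf}\; \varepsilon_{\lambda}\cdot
\Delta c(t),$$

with $d$ the source–detector distance, ppf a partial pathlength factor
(0.1 throughout, the value conventional in this pipeline family — note it
is small relative to typical differential pathlength factors, so absolute
µM scales are convention-dependent), and $\varepsilon$ the extinction
coefficients (bundled for 690/760/830/850 nm). Intensity is
$I = I_0 e^{-\Delta OD}$; optical density is recovered as
$-\ln(I/\bar I)$, which fixes the arbitrary baseline at the mean — all
downstream concentration *changes* are therefore defined up to an
additive constant, which the GLM's constant column and the epoch
detrend/baseline options absorb.

## The simulator

`sim_config()` fixes the study conditions: 17 subjects, 5.2 Hz raw
sampling, 20 trials per condition, inter-stimulus interval (offset to
next onset) uniform on [10, 20] s. Neural responses exist only in the two
STG regions: each event contributes a boxcar of the stimulus duration
convolved with the canonical HRF, scaled so an isolated event peaks at
the configured amplitude — 2 µM HbO for speech and 1 µM for noise by
default, echoing the ~1 µM speech–noise difference scale reported for
this paradigm, with HbR set to −HbO/3 (inverted and smaller, a
conventional ratio; configurable). Silence contributes nothing.

Systemic physiology is one shared trace per subject — a 0.1 Hz Mayer
wave (1 µM), a 1.1 Hz cardiac oscillation (0.5 µM) and a random-walk
drift — coupled into every channel with a per-channel gain drawn from
U[0.5, 1.5]. Short channels carry the systemic trace and noise but no
neural signal. A single shared trace with heterogeneous gains is the
simplest structure under which short-channel correction is useful but
not trivially exact. Sensor noise is AR(1) (marginal SD 0.4 µM,
coefficient 0.3) added per row in concentration space. The systemic and
noise defaults are conventional choices, not fitted to any dataset: the
paradigm this package emulates does not publish its measured noise
spectrum. Consequently, passing simulation tests demonstrates
correctness of the algorithms under this generative model, not
performance on any particular instrument's data — real recordings add
motion artifacts, non-sinusoidal and non-stationary physiology, and
optode-coupling variation that the simulator only caricatures (motion is
available only through the explicit `inject_artifact()` test utility).

One master seed fixes everything; subject $i$ uses seed + $i$, so any
session can be regenerated bit-identically.

## The averaging chain

`averaging_subject_estimates()` runs: resample to 3 Hz → optical density
→ scalp-coupling index (cardiac-band 0.7–1.45 Hz correlation between the
two wavelengths; channels below 0.8 dropped) → temporal-derivative
distribution repair (TDDR) → nearest-short-channel regression →
Beer–Lambert → 20–40 mm pruning → HbO/HbR anti-correlation enhancement →
0.01–0.7 Hz bandpass (transition widths 0.005 and 0.3 Hz) → epochs from
−3 to 14 s with a per-epoch linear detrend → rejection of epochs
exceeding 100 µM peak-to-peak → per-condition averages → ROI waveforms →
the 5–7 s window mean as the subject's response estimate. Group bands are
percentile bootstraps across subjects (subjects resampled with
replacement, 1000 draws, 95%).

Numerical notes, in the order they bit us while validating:

* **TDDR** follows the published reference implementation exactly — the
  0.5 Hz split, Tukey biweight (c = 4.685) on the MAD-scaled centred
  derivative, 50-iteration cap — and is validated against that reference
  to machine precision, including its zero-phase IIR edge convention
  (steady-state initial conditions, no padding). A consequence worth
  knowing: on a *noiseless* oscillation, the robust scale collapses onto
  the signal's own derivative distribution and legitimate slopes are
  shrunk by a few percent; with any realistic noise floor the weights sit
  at ~1 and inlier signal passes unchanged.
* **Detrend vs amplitude.** A linear detrend over a [−3, 14] s epoch that
  is mostly response removes a substantial part of that response (roughly
  a third to a half on clean data). This is intrinsic to the procedure,
  and it is why the averaging route reports systematically smaller
  amplitudes than the GLM — the same ~2:1 relation seen in this
  paradigm's published group results. The optional pre-stimulus baseline
  correction (`baseline = c(-3, 0)`, off by default) makes absolute epoch
  levels interpretable when the detrend is switched off.
* **Peak timing.** The canonical response to a ~5 s stimulus peaks near
  7.5–8 s after onset (boxcar ⊛ HRF oracle), so the fixed 5–7 s window
  deliberately under-reads the peak; it is kept because it is the
  paradigm's standard export.
* The ROI mean and the 5–7 s time mean are both unweighted, so their
  order does not matter.

## The GLM chain

`build_design()` constructs, per condition, either a canonical regressor
— a unit boxcar of the stimulus duration (or a fixed `boxcar_dur`)
convolved with the canonical double-gamma HRF (peak delay 6 s, undershoot
delay 16 s, dispersions 1 s, ratio 1/6, 32 s support; the standard
published constants) — or an FIR basis of 14 one-second sticks at integer
delays. Cosine drifts with frequencies $k/2T \le 0.01$ Hz plus a constant
complete the design. Two numerical choices matter:

* Canonical regressors are built on an oversampled (≥ 10 Hz) grid and
  decimated, so event onsets and the kernel peak are resolved accurately
  at coarse analysis rates; and they are scaled to **unit isolated-event
  peak**, which makes a fitted beta directly interpretable as a response
  amplitude in µM and comparable with the simulator's configured
  amplitudes.
* Short-channel nuisance variants: none, the short-channel mean (per
  chromophore), every short channel individually, or the first $k$ / all
  principal components of the centred short-channel matrix. PCA columns
  are left singular vectors, so all-PCs and all-individual-channels span
  the same space once the constant column is present and give identical
  condition betas up to numerics.

`fit_glm()` fits each channel by OLS, estimates AR(4) noise coefficients
from the residuals by Yule–Walker, filters data and design by
$1-\sum_i a_i z^{-i}$ in a single pass, and refits; SEs, t and two-sided
p values come from the whitened normal equations. A single whitening pass
(no iteration) is a deliberate simplification; the AR order is exposed.
One-sided (directional) p values are available where detection is
defined as a positive HbO response. ROI pooling weights channels by
1/SE (`inv_var` gives 1/SE² as an option); zero-SE exact fits are floored
so they share weight equally rather than producing indeterminate ratios.

For non-overlapping events the FIR estimate provably reduces to the
block average. The package's equivalence oracle constructs exactly that
situation — noiseless data, events on the analysis grid, and a kernel
whose support ends within the 14 s FIR span — and the two routes then
agree to numerical precision; with the default 32 s kernel the response
tail extends past the modelled window and leaks a small (~2% of peak)
bias into the comparison, which is why the oracle truncates the kernel
rather than loosening its tolerance.

## Detection evaluation

Channel-level p values over the STG channels form a detection table:
silence rows are the negative class, speech and noise rows the positive
class. The ROC sweeps the p threshold over all distinct values; AUC is
the trapezoid rule (identical to the Mann–Whitney statistic with ties
counted half, which the tests verify by brute-force enumeration), and
TPR at 5% FPR is read off by linear interpolation between vertices (a
step convention is available). Tables pool (subject × channel ×
condition) rows across the cohort; per-condition tables are a filter
away.

Sweep drivers refit the cohort per nuisance method, per sample rate, or
per boxcar duration. Two operating-point choices are documented rather
than hidden: the nuisance-method sweep is demonstrated on a cohort with
*strong* systemic contamination (Mayer amplitude 8 µM, drift scale 0.3
µM/√sample — several times the neural signal), because at the default
contamination every method saturates the ROC and the comparison is
vacuous; likewise the boxcar sweep uses a noisier cohort (sensor SD 2 µM)
so the ROC sits mid-range and duration differences are visible. Problem
sizes in the bundled validation (10 and 8 subjects for the sweeps, 17
for parameter recovery, 2000 channel fits for null calibration) were
chosen as the smallest cohorts at which the qualitative orderings are
stable across seeds.

## Group inference

Per-subject estimates (from either route) enter linear mixed models with
a subject random intercept: a cell-means summary model
(`estimate ~ -1 + condition:roi:chroma + (1|subject)`), the
speech-versus-noise contrast over the combined STG
(`estimate ~ condition + (1|subject)`, per chromophore), and the
left-versus-right lateralization contrast on speech
(`estimate ~ roi + (1|subject)`). Estimation is REML via `lme4`; fixed
effects are tested with Wald statistics referred to a t distribution
with (subjects − fixed effects) degrees of freedom, which matches the
exact paired t-test in the balanced two-level case and keeps the
17-subject null close to nominal (a plain normal reference is visibly
anticonservative there). A degenerate random-intercept variance falls
back to ordinary least squares with a logged note.
`agreement_report()` runs both contrasts for several sources and flags
whether they reach the same conclusion (sign and significance at α =
0.05, no multiplicity correction — a known limitation of the paradigm's
reporting style that we reproduce rather than fix).

## Spectral quality control

`qc_report()` overlays three spectra: the Welch periodogram of the raw
data (Hann windows, 50% overlap), the spectrum of the expected response
(events ⊛ HRF — for this design the power concentrates near 0.05 Hz, the
mean presentation rate), and the analytic magnitude response of the
bandpass filter. It flags a filter that attenuates the expected-response
peak by more than 3 dB or the cardiac peak by less than 20 dB. The
filter itself is a Hamming-windowed linear-phase FIR with a
piecewise-linear target response, length set by the narrower transition
band (3.3 cycles) and capped by the data length, applied zero-phase by
centred convolution with symmetric padding.

## Worked example

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)                 # 17 sessions + ground truth

est <- glm_subject_estimates(cohort)           # 0.6 Hz, 3 s boxcar, all PCs
condition_contrast(est)                        # speech - noise, per chroma
lateralization_contrast(est)                   # right - left STG, speech

avg <- averaging_subject_estimates(cohort)     # full averaging chain
agreement_report(list(averaging = avg, glm_corrected = est))

sw <- sweep_nuisance(simulate_cohort(
  sim_config(mayer_amp = 8, drift_scale = 0.3, seed = 2), 1:10))
vapply(sw, function(r) r$tpr_at, 0)            # detection per method
```

## Known limitations

* I/O is the package's plain-text fixture dialect (wide CSV plus event
  and montage sidecars); the HDF5-based community container is not read
  or written.
* The simulator's systemic model is a single shared trace; real systemic
  physiology is spatially structured, and results on correction-method
  *rankings* transfer to real data only qualitatively.
* Extinction coefficients and wavelengths are conventions (760/850 nm by
  default); absolute µM values shift under other tables, though all
  contrasts and detection results are invariant to that rescaling.
* Second-level p values depend on the chosen reference distribution;
  with 17 subjects the difference between t- and z-references is
  material, and we chose the t.
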