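# fnirsblock

Analysis of **passive block-design auditory fNIRS** recordings in R:
epoch averaging and GLM analysis, short-channel systemic correction,
ROC-based detection evaluation, and mixed-effects group inference —
driven by a forward simulator with known ground truth.

## The scientific problem

Auditory fNIRS studies present short sounds (speech, noise, silence) in
a block design and ask (i) whether a cortical response can be detected,
(ii) how large it is, and (iii) whether conclusions depend on the
analysis route. Two routes coexist in the field:

* **Averaging** — epoch the hemoglobin time series around each stimulus
  onset (−3 to 14 s), detrend, reject artifacts (100 µM peak-to-peak),
  average per condition, and summarize the region-of-interest waveform
  by its 5–7 s mean.
* **GLM** — regress the whole recording on model responses: a boxcar of
  the stimulus duration convolved with the canonical double-gamma HRF
  (or a 14-component FIR basis for shape-free deconvolution), cosine
  drifts up to 0.01 Hz, and short-channel nuisance regressors, with an
  AR(4) prewhitened least-squares fit
  (`ΔOD_λ = d · ppf · ε · Δc`, ppf = 0.1, for the optical model).

Detection is scored with ROC curves in which the **silent control
condition defines false positives**; the headline metric is the true
positive rate at 5% false positives. Group questions (speech > noise?
left/right asymmetry?) use linear mixed models
(`estimate ~ condition + (1|subject)` and `estimate ~ roi +
(1|subject)`, per chromophore).

Everything runs against a simulator that reproduces the paradigm's
design — 17 subjects, 5.2 Hz, 24 long + 8 short channels on a standard
10-05 montage, 20 trials per condition, 10–20 s inter-stimulus
intervals, neural responses confined to superior temporal gyrus
channels, systemic physiology shared with short channels — so every
stage can be validated against known truth. See the vignette
(`vignettes/block-design-analysis.Rmd`) for the model, parameter
choices, and limitations.

## Worked example

```r
library(fnirsblock)

cfg <- sim_config(seed = 1)          # the study conditions
cohort <- simulate_cohort(cfg)       # 17 sessions with ground truth

# canonical GLM at 0.6 Hz, 3 s boxcar, all short-channel PCs as nuisance
est <- glm_subject_estimates(cohort)
condition_contrast(est)
#>   chroma      delta          se            p
#> 1    hbo  1.0113351 0.004974382 3.190764e-27
#> 2    hbr -0.3438808 0.003260540 5.976395e-23
```

The HbO response to speech is estimated ~1 µM larger than to noise
(the simulated truth is a 1 µM peak difference) and the HbR difference
is inverted and about a third the size, both far below the 0.05
significance level. Detection performance per correction method:

```r
sw <- sweep_nuisance(simulate_cohort(
  sim_config(mayer_amp = 8, drift_scale = 0.3, seed = 2), 1:10))
round(vapply(sw, function(r) r$tpr_at, 0), 3)
#>             none       short_mean short_individual      short_pca_1
#>            0.979            1.000            1.000            1.000
#>      short_pca_2      short_pca_4    short_pca_all
#>            1.000            1.000            1.000
```

Under strong systemic contamination every short-channel method pushes
the true-positive rate at 5% false positives to ceiling while the
uncorrected analysis falls short, and the full-rank variants (mean,
individual channels, all PCs) agree with one another — the qualitative
pattern this analysis family reports on real data.

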