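---
title: "Camera oximetry with oxicam: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera oximetry with oxicam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxicam)
```

## The measurement problem

A smartphone camera pressed against a fingertip, with the flash on, records
a reflectance photoplethysmogram (PPG): each heartbeat pushes a surge of
blood into the finger, the blood absorbs light, and the frame brightness
dips. Oxygenated and deoxygenated hemoglobin absorb differently across the
visible spectrum, so the *relative* pulsatile amplitude in the red, green
and blue channels carries information about the oxygen saturation of
arterial blood (SpO2). `oxicam` implements a complete research pipeline
around this idea:

1. a **synthetic cohort generator** that emulates a varied-FiO2
   desaturation study (stair-stepped SpO2 descents, two hand-records per
   subject, camera rendering with per-channel gains and 8-bit clipping);
2. **signal extraction** from frame stacks (full-frame channel means);
3. **preprocessing** into fixed-length labeled windows with leakage-safe
   standardization;
4. a small **convolutional network** regressing SpO2 from 3 s of
   three-channel signal, trained and evaluated by leave-one-subject-out
   cross-validation (LOOCV);
5. a classical **ratio-of-ratios** baseline with linear calibration;
6. an **evaluation suite**: MAE / A_rms / R-squared, Bland-Altman limits of
   agreement, hypoxemia screening ROC analysis, a label-floor ablation, and
   paired signed-rank comparison.

Everything is driven by explicit configuration objects and a single seed,
so every number the package produces is reproducible.

## The forward optical model

The generator works backwards from the physics the estimators assume. For
channel $c \in \{R, G, B\}$ with camera gain $g_c$, baseline reflectance
$\mathrm{DC}_c$ and a zero-mean periodic pulse waveform $w(t)$:

$$ s_c(t) = g_c\,\Big[\mathrm{DC}_c\,(1 + \delta) -
  \mathrm{AC}_c(S(t))\,(1 - \kappa)\, w(t)\Big] + \varepsilon_c(t), $$

$$ \mathrm{AC}_c(S) = \mathrm{DC}_c \,\pi_0\,
   \frac{\epsilon_{\mathrm{HbO_2},c}\,S + \epsilon_{\mathrm{Hb},c}\,(1-S)}
        {\mu_{\mathrm{ref}}}, $$

where $S$ is the saturation fraction, $\pi_0$ the pulsatility (default
0.2), $\mu_{\mathrm{ref}}$ a channel-common normalizer, $\kappa$ the
callus damping and $\delta$ the DC elevation of a subject's tissue, and
$\varepsilon_c$ sensor noise. The pulse enters negatively - systole absorbs
light, reflectance dips. Because the AC/DC fraction of every channel is
proportional to the blood's effective absorption with the *same* constant,
the classical two-wavelength ratio of ratios

$$ R = \frac{\mathrm{AC}_R/\mathrm{DC}_R}{\mathrm{AC}_G/\mathrm{DC}_G}
     = \frac{\epsilon_{\mathrm{HbO_2},R}\,S + \epsilon_{\mathrm{Hb},R}\,(1-S)}
            {\epsilon_{\mathrm{HbO_2},G}\,S + \epsilon_{\mathrm{Hb},G}\,(1-S)} $$

is *exactly* invertible on generator output in the noiseless limit
(`spo2_from_ratio()` is the closed-form inverse). This is the package's
central oracle: the test suite demands agreement within 0.1% SpO2 over the
70-100% grid, and gets it to well under 0.05%.

Default extinction coefficients are published whole-blood molar extinction
values at effective wavelengths 660/530/470 nm. Real camera channels have
broad, sensor-specific spectral responses, so these defaults are
configuration (`optical_model()`, `ror_config()`), not constants. The
defaults place roughly two orders of magnitude more absorption in green and
blue than in red, which is why the camera model defaults to per-channel
gains of (1, 3, 18): without amplification the blue channel would be
quantized into uselessness by 8-bit storage.

### Pulse morphology

No specific beat shape is assumed by the estimators, so the generator uses
the simplest smooth waveform with the right qualitative anatomy: a sum of
two wrapped Gaussians per period (dominant systolic peak, smaller dicrotic
wave), heart-rate independent in phase units (`waveform_params()`). The
analytic period mean is subtracted in synthesis so the pulsatile term
cannot bias the DC level. Heart rate is fixed per subject (default 70 bpm):
the windows are long enough (3 s) to contain 2-4 beats at any plausible
resting rate, and rate itself is deliberately not an informative feature in
the generator.

### The desaturation protocol

`protocol_config()` describes the study-shaped trajectory: a resting
segment at baseline SpO2 (default 98%), then one plateau target drawn
uniformly inside each of the ranges (93,100], [89,93], [80,88], [70,79],
visited in descending order, connected by a first-order lag (time constant
20 s - an SpO2 response to a step change in inspired oxygen is gradual)
and each held at least 30 s. The default 15-minute session sits inside the
14-19 min range typical of such protocols. Gas physiology is not modeled;
only the SpO2 trajectory matters downstream, so it is simulated directly.

### Between-subject variation

By default subjects differ in their SpO2 trajectory (independently drawn
plateau targets), cardiac phase, and per-record sensor noise. Two further
sources of variation are available but must be asked for:

* **Callused skin** - the `(0.5, 0.5)` preset of `subject_profile()`
  halves the pulsatile amplitude and raises the baseline 1.5x, the
  signature of thickened fingertip tissue; inject it for chosen subjects
  via the `profiles` argument.
* **Amplitude jitter** - `generate_cohort(subject_variation = c(b, p))`
  draws a per-subject brightness factor and pulsatility factor (uniform,
  half-widths `b` and `p`, applied as common factors across channels:
  tissue thickness and contact pressure scale all channels together
  rather than reshaping the relative spectrum).

Amplitude jitter is off by default for an identifiability reason worth
stating plainly: a subject-level amplitude factor cannot be estimated from
the handful of training subjects a leave-one-subject-out fold provides, so
any jitter level translates directly into an irreducible affine error on
the held-out subject (with +/-10% jitter, held-out predictions still
correlate above 0.9 with truth but carry offsets of several % SpO2). That
is a faithful miniature of the real cross-device, cross-skin calibration
problem - and exactly why it is an explicit experimental knob rather than
a hidden default: the default cohort measures whether the pipeline
recovers the optical encoding; the knob measures how performance degrades
when subject-level confounds are introduced.

### What the generator does not emulate

Motion artifacts, ambient-light drift, auto-exposure dynamics (the
emulated capture locks its settings), sensor-specific spectral response,
and any physiologic coupling between heart rate and desaturation. Passing
tests on synthetic cohorts therefore demonstrates that the *pipeline* is
correct and leakage-free and that the models can recover the optical
encoding they assume - not that the trained network transfers to real
fingers. The `load_external_dataset()` adapter exists so the identical
pipeline can be pointed at real recordings exported as per-record CSVs.

## Preprocessing

A reference reading at time $t$ owns the frames whose timestamps fall in
$[t - w/2, t + w/2)$ - half-open and left-inclusive, so a 3 s window at
30 fps is *exactly* 90 frames regardless of alignment. Windows crossing a
record boundary are dropped, as are readings below 70% SpO2 (outside the
validated range of transfer-standard oximeters) - before any statistics
are computed.

Channel-wise normalization statistics are length-weighted combinations of
per-subject moments (weights proportional to recording seconds, hands
pooled within subject), computed on the training partition only. The
trained model bundles its statistics and applies them at prediction time;
`predict_spo2()` refuses pre-standardized input precisely so that test
data can never contribute to normalization.

## The network

`model_spec()` defaults: three convolutions (16, 32, 64 filters) and two
linear layers (64, 1). The first convolution is two-dimensional over
(time, color) with a 3x3 kernel and no padding - 90x3 in, 88x1 out per
filter - so color mixing happens once, up front; the remaining
convolutions are 1-D over time (kernel 3, no padding: 88 to 86 to 84).
ReLU throughout; 352,129 parameters in total (the test suite pins this
against a layer-by-layer count). These widths are the smallest shapes
consistent with the intended three-conv/two-linear design and a scalar
head; all are configurable.

Training (`train_cnn()`) minimizes MSE with Adam; L2 regularization is
applied inside the optimizer as weight decay on weights, not biases. The
output bias is initialized at the training-label mean, so the untrained
network *is* the mean predictor and training learns deviations from it.
The checkpoint with the lowest validation MAE is returned, with the full
per-epoch log. Gradients are clipped to a global L2 norm of 10 per step
(`grad_clip`); without clipping, the compressed desk-scale schedule below
can diverge outright on some seeds, while the reference schedule's
gradients never approach the ceiling. Forward and backward passes are
implemented as accumulated BLAS matrix products (one per kernel offset);
the gradients are verified against finite differences in the test suite to
~1e-6 relative error.

The reference schedule (`train_config()` defaults) is learning rate 1e-5
with a one-time decay by 0.1 after epoch 80, L2 strength 0.1, and 120
epochs - appropriate for thousands of training windows and patient
wall-clock budgets. For desk-scale work `desk_experiment_config()`
substitutes a compressed schedule (3e-3, batch 64, 25 epochs, same L2):
with the output-bias initialization the compressed schedule reaches
held-out MAEs a factor of 4-5 below the mean-predictor baseline on the
scaled cohort in about a minute per fold on one CPU core.

### Cross-validation

`loocv_cnn()` runs one fold per subject: the test subject is fully
excluded from training, validation and normalization; the validation
subject is the next subject in a fixed rotation (the choice is arbitrary
but must be deterministic; a rotation exercises every subject as validator
exactly once across folds). Hard assertions (`assert_no_leakage`) fire if
a fold's test subject appears anywhere upstream. Headline MAE is the
unweighted mean of per-fold MAEs.

## The ratio-of-ratios baseline

Each 3 s window is segmented into beats on the inverted signal (the pulse
is a reflectance dip, so "systolic peak height" is trough depth). Peak
detection uses local maxima with prominence at least 0.3x the window
inter-quartile range and separation at least 0.4 nominal beat periods;
beats are delimited by diastolic minima, and beats truncated by the window
edge are dropped. AC is the mean systolic dip depth over complete beats;
DC is the mean channel level over the *span of complete beats* - an
integer number of cardiac periods, over which the zero-mean pulse
integrates away, where a plain window mean would be biased by the partial
beat at the window edge (a `dc_scope = "window"` option preserves the
plain convention). Windows with fewer than 2 complete beats are flagged
unstable and excluded from fitting and evaluation, with counts logged.

Raw SpO2 from the inversion is then calibrated by ordinary least squares
against ground truth using the raw estimate and the three channel ranges
as features (per-channel mean upslopes are extracted and can be included
via a flag), fit on training folds only, under the same subject splits as
the CNN, and reported through the same result structure.

## Evaluation conventions

* **R-squared** is the squared Pearson correlation, not the regression
  coefficient of determination; the two differ for biased predictions, and
  the correlation convention is the one usually quoted alongside camera
  oximetry regressions.
* **Bland-Altman** limits of agreement are $1.96 \times \mathrm{sd}$ of
  the differences, sample convention ($n-1$; differences $(-1,0,1)$ give
  LOA exactly 1.96), with a population-convention flag. Skewness of the
  differences is reported so the normality assumption can be checked.
* **Screening** uses strict inequality: truth below the *classification
  threshold* defines a positive; prediction below the *decision boundary*
  defines a predicted positive; values exactly at a cut count as not
  below.
* **ROC curves** sweep the decision boundary over 70-100, average
  fold-level TPR/FPR at each boundary (degenerate folds excluded from the
  affected average, with a note), append the trivial endpoints, and
  integrate by trapezoid. The recommended operating point is the boundary
  closest to the ideal (0,1) corner. The test suite checks the trapezoid
  AUC against the pairwise-comparison probability estimator.
* **Signed-rank** comparisons (e.g. per-subject MAE of two methods) use
  the exact distribution; six all-positive differences give the minimal
  one-sided p of $1/64$, which the suite verifies by enumerating all
  $2^6$ sign patterns. All-zero differences are degenerate and reported
  as such (p = 1, flagged).
* **Ablation**: `ablation_study()` removes all samples below a floor from
  training and evaluation alike, re-runs the full LOOCV per floor
  (default floors 70/75/80/85), and reports MAE and agreement per floor -
  quantifying how much of the headline error lives in the deep
  desaturation range that many evaluation protocols never probe.

## Numerical and reproducibility choices

* Gains and frame rendering quantize by round-half-up and clip to the
  representable range; `detect_clipping()` reports per-channel saturated
  fractions and flags channels above a threshold (default 1%).
* Frame extraction with zero spatial noise is quantization-exact; with
  spatial noise the per-frame error of a full-frame mean is bounded by
  $\sqrt{\sigma^2 + 1/12}/\sqrt{N_{\mathrm{pix}}}$ (spatial noise plus
  quantization variance), which the tests enforce at 5 standard errors.
* One experiment seed fans out deterministically to per-stage seeds via a
  stage-name hash, so adding a stage never reshuffles existing ones;
  re-running a seeded experiment reproduces `reports.json` byte-for-byte
  (timestamps live only in the run log). Trained folds are cached keyed
  by a hash of the upstream configuration, so evaluation-only changes
  never retrain.
* Problem sizes used by the shipped checks: the desk-scale cohort is 6
  subjects x ~4 min (four 55 s plateau intervals plus a 20 s resting
  lead-in), about 2,850 windows, trained for 25 epochs per fold - chosen
  as the smallest configuration on which cross-subject recovery is
  unambiguous; the full-length defaults remain the 15-minute protocol and
  the patient schedule above.

## Known limitations

* The CNN learns the generator's optical encoding; absolute accuracies on
  synthetic cohorts say nothing quantitative about real skin, sensors, or
  motion.
* The ratio-of-ratios inversion assumes the generator's two-chromophore
  model with shared normalization; on real data its raw output is useful
  mainly as a calibration feature, which is exactly how the baseline
  consumes it.
* Beat segmentation is tuned for resting heart rates (40-120 bpm with the
  default separation constraint) and clean contact PPG; it is not an
  arrhythmia-robust detector.
* `wilcox.test`'s exact path cannot handle tied difference magnitudes; with
  ties it falls back to the normal approximation with a warning.
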