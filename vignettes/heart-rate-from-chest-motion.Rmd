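---
title: "Estimating heart rate from six-axis chest motion"
author: "seismoHR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heart rate from six-axis chest motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seismocardiography (SCG) measures the micro-vibrations that cardiac
contraction and blood ejection imprint on the chest wall. A clip-on
six-axis motion sensor — tri-axis accelerometer plus tri-axis gyroscope —
can therefore monitor heart rate with far less measurement burden than ECG
electrodes. The obstacle is motion artifact: posture shifts, walking and
running bury the cardiac component under interference that is orders of
magnitude larger. Classical pipelines hand-design filters for each
condition; the approach implemented here instead trains a 1-D
convolutional network to regress heart rate directly from fixed-size
motion windows, letting the convolutional stack learn its own filters.

`seismoHR` implements that pipeline end to end, together with a synthetic
data generator that stands in for human recordings, so every stage is
testable with known ground truth.

## Pipeline and model

A paired recording session consists of six-axis chest motion sampled at an
irregular rate between 100 and 200 Hz and a single-lead ECG at 512 Hz that
supplies ground-truth labels. Processing follows a fixed stage order:

1. **Cubic-spline resampling** of the motion channels to a uniform 256 Hz
   grid (`resampleCubic()`; the "fmm" end condition reproduces cubic
   polynomials exactly).
2. **Savitzky–Golay subtraction** (`removeMotion()`): the large-range
   motion trend is estimated per channel by a least-squares polynomial
   smoother of order 2 over 31 samples (~121 ms at 256 Hz) and subtracted,
   leaving the cardiac band intact.
3. **Normalization** to zero mean, unit variance per channel
   (`zNormalize()`, population 1/n convention so idempotence is exact).
4. **Windowing** (`windowize()`): sliding 5 s windows at a 1 s stride;
   each window carries 6 channels x 1280 samples. The ECG is labeled with
   Pan–Tompkins QRS detection (`detectRPeaks()`) and each window's label
   is 60/mean(RR) over the RR intervals wholly inside it. Labels below 60
   or above 200 bpm are treated as ECG artifacts and the window is
   dropped.
5. **Split**: windows are pooled, shuffled with a stated seed, and sliced
   70/10/20 into train/validation/test.

The regressor is a 1-D adaptation of VGG: 1x3 convolutions with rectified
linear activations, five stages separated by 1x2 max-pooling (so 1280
samples become a length-40 feature map), then three fully connected layers
with dropout 0.5 on the two hidden ones and a single linear output node.
Depth variants VGG-11/13/16/19 carry 8/10/13/16 convolutional layers.
Training minimizes the L2 loss with Adam (reference learning rate 1e-4,
128-sized minibatches, Xavier-initialized weights), evaluates the
validation cost every epoch, and keeps the parameters from the epoch with
the lowest validation cost. The production configuration is the ensemble
averaging a VGG-16 trained without augmentation and a VGG-19 trained with
augmentation:

```{r}
library(seismoHR)
specs <- standardConditions(durationS = 180, seed = 1)
sessions <- lapply(specs, simulateSession)
ds <- buildDataset(sessions, shuffleSeed = 1)
aug <- augmentDataset(ds, augmentationPolicy())
a <- trainModel(modelSpec("vgg16"), ds, trainHyper(), tag = "vgg16_noaug")
b <- trainModel(modelSpec("vgg19"), aug, trainHyper(), tag = "vgg19_aug")
pred <- predictHR(ensembleModel(a, b), ds, split = "test")
errorMetrics(hrLabels(ds)[splitTags(ds) == "test"], pred)
```

Augmentation (`augmentDataset()`) expands only the training split with
three label-preserving operators, composed per copy as scaling, then
jittering, then circular permutation: `scaleWindow()` multiplies by
`1 + alpha`; `jitterWindow()` adds zero-mean Gaussian noise of SD `alpha`;
`permuteWindow()` rotates the window circularly by an integer shift. A
circular shift moves the temporal location of the beats without changing
their number, additive noise and amplitude scaling leave beat timing
untouched, so all three leave the heart-rate label valid by construction.

## Evaluation

`errorMetrics()` reports the mean relative accuracy
`100 (1 - mean(|est - ref| / ref))`, MAE, SDAE (population SD of absolute
errors), RMSE and Pearson correlation; `blandAltman()` gives the mean
difference and 95% limits of agreement at ±1.96 population SD of the
differences. `aTest()` quantifies structural risk: for every fold count z
from 2 to 10, heart-rate-stratified z-fold cross-validation is run with
the supplied training procedure, the regression error tau(z) is the mean
held-out MAE, and the summary tau-hat averages tau(z) over the 9 fold
counts; the minimum tau indicates the headroom a larger dataset could
unlock. `stratifiedFolds()` deals consecutive sorted label runs
round-robin so every fold sees the full heart-rate range.

## The synthetic-data generator

No public corpus of paired six-axis SCG + ECG exists, so the `simulate`
module generates one with controllable ground truth. Its defaults define
the measurement conditions used throughout the package's tests:

* **Beat times** (`makeBeatTimes()`): gaps follow 60/hr(t) for a
  programmable trajectory, times a multiplicative RR jitter with
  coefficient of variation 0.02 — the low end of resting sinus
  arrhythmia, so labels are well defined at the 5 s window scale.
* **ECG** (`simulateEcg()`, 512 Hz): each beat renders a stereotyped
  biphasic QRS (~80 ms, template maximum exactly at the beat time) plus
  low-amplitude P/T bumps whose offsets shorten with the local RR
  interval, as the PQ and QT segments do physiologically; white noise of
  SD 0.02 relative to the unit R peak.
* **Motion** (`simulateMotion()`): per beat, each channel receives a
  damped oscillation (carrier drawn from 10–30 Hz, ~150 ms envelope) —
  the simplest waveform with SCG-like band structure; per-channel gains
  and carriers differ so the six axes are informative but redundant.
  Interference is slow (< 0.5 Hz) baseline drift for posture conditions,
  or gait harmonics for treadmill conditions at a speed-to-cadence map
  (3.2→1.7 Hz up to 10.3→3.0 Hz, from standard human cadence ranges) with
  two harmonics and random phases. White sensor noise carries ~20% of the
  interference power. The interference-plus-noise mix is rescaled so the
  cardiac-to-interference power ratio matches `snrDb`; the default of
  6 dB describes a snug chest mount where the cardiac pulse is visible
  but clearly contaminated. The sampling rate is drawn uniformly from
  100–200 Hz per session, exercising the resampler exactly where the
  pipeline needs it.
* **Conditions** (`conditionSpec()`, `standardConditions()`): the 12-way
  grid of 2 physical states x 3 postures plus 6 treadmill speeds. Relaxed
  profiles wander in 60–90 bpm, aroused in 100–180 bpm; the generator
  accepts 40–220 bpm so the 60–200 keep-range exclusion is exercised.

What the generator does *not* model — and hence what green tests do not
demonstrate about real data: true SCG morphology (AO/AC fiducials),
respiration, sensor saturation, electrode artifacts, posture-dependent
coupling changes within a session, and between-subject morphology
variation. Results on this corpus validate the pipeline's mechanics and
learnability, not clinical performance.

## Numerical and design choices

Where the method admits more than one reasonable reading, the package fixes one choice, once:

* **Stage order** resample → detrend → normalize → window, with
  Savitzky–Golay applied at 256 Hz so the 31-sample window spans ~121 ms.
* **Normalization scope**: per channel *per window* (the network consumes
  windows, and normalization belongs to window formatting); per-recording
  normalization is available as `normalizeScope = "recording"`.
* **Savitzky–Golay edges**: one-sided truncated-window fits — no data is
  fabricated by padding; the filter interior is the standard centre-row
  projection and is verified in tests against an independent per-window
  `lm()` oracle.
* **Window-label rule**: only RR intervals with both endpoints inside the
  window enter the mean; intervals spanning an edge are excluded. At 5 s
  windows the alternative (counting overlapping intervals) differs by
  under 1 bpm.
* **Pan–Tompkins constants**: band-pass 5–15 Hz (zero-phase Butterworth),
  150 ms integration window, 200 ms refractory, threshold adaptation
  factors 0.125/0.25 with search-back at half threshold — the published
  algorithm's standard values, all exposed as arguments. Thresholds adapt
  to the signal level, so detection is amplitude-scale invariant.
* **SD conventions**: population (1/n) for SDAE, Bland–Altman and
  normalization, making invariants bit-testable.
* **Augmentation defaults**: shift uniform over \[0, n), jitter SD
  uniform in \[0.05, 0.2\] post-normalization units, scaling ratio
  uniform in \[-0.1, 0.1\], one copy per training window. Mild,
  label-safe, and configurable; parameters are drawn per copy.
* **Output-bias initialization**: the single output node's bias starts at
  the mean training label (weights remain Xavier). A randomly initialized
  regressor first spends many updates shifting its output to the label
  scale (~120 bpm); starting at the mean removes that dead time without
  touching the architecture. Disable with `centerOutputBias = FALSE`.
* **Split counts**: `round(0.7 n)` / `round(0.1 n)` / remainder, assigned
  by shuffling indices under a stated seed. The default split does not
  group by subject — windows of one subject can appear in both train and
  test, which reproduces the plain shuffled protocol but admits subject
  leakage; `bySubject = TRUE` provides the grouped alternative.
* **Dataset container**: a single Feather (Apache Arrow) file — standard,
  portable and lossless for large numeric arrays; shape and split
  metadata round-trip bit-exactly as attributes.

## Desk-scale configurations

Full-width VGG training on tens of thousands of windows is a GPU
workload. The package's own experiments run on one CPU core by scaling
width, not topology: `widthMultiplier = 0.0625` keeps every layer count
and shape invariant while cutting compute ~250-fold. The test suite's
learnability experiment uses ~2,000 windows (constant-rate 60 s sessions,
heart rate uniform in 60–180 bpm, generator defaults), a 0.0625-width
VGG-11, learning rate 1e-3 and 30 epochs; the structural-risk demo uses
600 windows with Zmax = 3. The raised learning rate compensates for the
~250-fold smaller parameter count — at width 1 the reference 1e-4 applies.
These problem sizes were chosen so a full test run stays comfortable on a
laptop core while still exercising real learning rather than
memorization.

## Known limitations

* The compiled conv/pool kernels assume kernel 3, stride 1, "same"
  padding and pool 2 — exactly the VGG family here, nothing more general.
* Exact bitwise reproducibility holds for a fixed BLAS; across different
  BLAS builds, results match to numerical tolerance only.
* The Pan–Tompkins implementation targets clean-to-moderately-noisy ECG;
  it has no ectopic-beat rejection, and the generator's ECG does not
  exercise pathological morphologies.
* `aTest()` retrains sum(z) models; at Zmax = 10 that is 54 trainings.
  Use reduced widths/epochs (`cnnTrainer()`), or a smaller Zmax, for
  desk-scale runs.
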