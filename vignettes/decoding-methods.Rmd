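---
title: "Decoding individual finger activation from HD-sEMG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding individual finger activation from HD-sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fingerdecode)
```

## The decoding problem

A high-density grid of 8 × 24 monopolar electrodes (10 mm pitch,
2048 Hz) over the forearm records the activity of the extrinsic finger
muscles. The decoding task is nine-way: four fingers × two movement
directions (flexion/extension) plus rest, with a *proportional* output
— the estimated activation level of the decided finger, in newtons of
fingertip force (offline) or percent of maximum voluntary contraction
(MVC, online). Every decoder in this package consumes the same
preprocessed signal: per-channel RMS over 200 ms windows with 50 %
overlap.

## Windowing and time alignment

One window every 100 ms gives a 10 Hz feature stream, matching the
10 Hz force recordings. Because 0.1 s × 2048 Hz = 204.8 is not an
integer number of samples, frames are anchored to the nominal 100 ms
grid rather than to integer sample strides: frame *k* covers the
samples in `[k·0.1 − 0.2, k·0.1)` seconds (204 or 205 samples), and the
last partial window is dropped, so a recording of duration *T* yields
exactly `floor((T − 0.2)/0.1) + 1` frames. For metrics, the frame
ending at *t* is paired with the force/reference sample at its window
centre *t* − 0.1 s.

## The three decoders

**CSP-PE.** For each unordered class pair *(a, b)*, with `S_c` the
*uncentered* second-moment matrix of class-*c* RMS vectors, the filter
`w_a` solves `S_a w = λ (S_a + S_b) w` at the largest generalized
eigenvalue (and `w_b` at the smallest). Uncentered moments, rather than
mean-removed covariances, are deliberate: RMS features are non-negative
and magnitude *is* the discriminative quantity, which also lets rest
contrast with active classes through energy alone. One filter per class
per pair keeps the fused quantity scalar. The per-pair squared response
`(wᵀx)²` is normalised so its mean over the class's top-level training
frames is 1, and a class's fused score is the **minimum** over all its
pairwise competitions — losing a single contrast collapses the score,
which is what suppresses false co-activations. A final per-class scale
makes the mean fused score at the top calibration level exactly 1, so
the decoded level `100 · s · level_scale` reads in % MVC. The precise
fusion scheme of the original multi-class estimator is not fully
specified in the source literature; the construction here (squared
response, per-pair normalisation, min fusion) is a reconstruction of
the described penalisation behaviour and should be read as such.

Two consequences of this construction matter in practice:

- Because RMS baselines never vanish, every filter responds even at
  rest, and the rest class's own fused score stays near 1 everywhere.
  The rest decision therefore uses the model's rest-score statistics:
  a frame is rest unless the winning class's fused score exceeds that
  class's rest-frame mean + 3 sd. This keeps `x = 0 → rest` exact and
  makes the active/rest boundary scale-equivariant.
- The fused score is quadratic in the underlying activation (the
  response is a squared linear form), so for offline force decoding
  each class's signed force gain is fitted by through-the-origin least
  squares of recorded force on the *square root* of the fused score
  over the training tasks.

**LDA.** Gaussian class-conditional model with class means and a single
pooled covariance; the Bayes rule reduces to linear discriminants.
Priors are empirical class frequencies (the design leaves them open;
empirical frequencies are the standard choice). The offline
proportional value is a per-class ordinary-least-squares map from the
full RMS vector to the active finger's signed force, emitted
winner-take-all and floored at zero in the decided direction; online,
it is the decided class's hotspot subset mean scaled to % MVC. Whether
the force regression should use the full vector or a class-specific
subset is not specified; the full vector is used.

**THR.** Hotspot subsets stand in for the experimenter's visual
selection: the k = 5 channels with the highest class-mean RMS,
excluding channels that rank top-k for more than one class (such
channels lie in the intersection of maps and are assigned to neither;
no refill — a starved class keeps fewer channels, with a warning).
Thresholds maximise frame-wise one-vs-rest balanced accuracy over a
50-point scan between the rest-frame subset mean and the maximum subset
mean, taking the midpoint of the accuracy-maximising plateau.
"Maximising the correct classification" is not otherwise defined;
balanced accuracy is the implemented reading. Two flags mark
uncontrollable movements: a degenerate calibration (rest mean ≥ active
mean), and a competition recall below 0.75 — replaying the full
crossing + highest-mean rule on the calibration frames, a movement
recovering fewer than three quarters of its own frames cannot be
reliably elicited. The 0.75 bar sits in an empirically bimodal gap:
with overlapped maps the impaired movements score 0.50–0.72 while
normal movements score ≥ 0.87.

Ties anywhere (fused scores, discriminants, subset means) resolve in
favour of rest, then canonical class order — documented and
deterministic.

## Segmentation and outlier rules

A contraction cycle runs from the upward crossing of 10 % of the
finger's maximum force to the return below it. Two rules reject
atypical cycles: the duration band `|T − T̄| > 2.58 σ` (population σ;
the printed one-sided form of this band is dimensionally inconsistent,
so the symmetric band is implemented), and the amplitude rule — a
regression line over cycle index fitted to plateau midpoints (square
profiles) or vertices (triangles), rejecting cycles with
`|residual| > 1.96 · MSE`. The MSE (not RMSE) comparison is kept as
printed even though its units are awkward; both rules carry a 1e-9
relative numeric-noise floor so that bit-identical cycles are never
rejected (residuals of an exactly constant trend are ~1e-16 while the
MSE bound is ~1e-32). The regression's MSE is computed per task, and
smoothing (the five-sample forward moving average, truncated at the
tail) is applied once to decoded traces, upstream of all trace metrics.

## The synthetic subject

No recordings are distributed with this protocol, so evaluation runs on
a generative model designed to be controllable rather than
physiological:

- each movement class has a unit-peak Gaussian activation map (blob) on
  the grid; flexion classes on one half, extension on the other,
  centres ≥ 3 pitches apart; blob σ = 3 pitches, so neighbouring maps
  genuinely overlap;
- EMG is amplitude-modulated Gaussian noise: channel sd = baseline
  (5 µV) + Σ gain·map·activation, gain 150 µV at 100 % MVC — typical
  HD-sEMG magnitudes;
- blob centres drift slowly (Ornstein–Uhlenbeck, sd 1 pitch, τ = 5 s),
  emulating the trial-to-trial spatial variability of real activation
  patterns; without it, decoding is unrealistically easy (no
  cross-finger confusion at any subset size, false-activation floors
  ~0.1 %);
- commanded activations couple across fingers through an enslaving
  matrix (0.15 adjacent, 0.05 next-adjacent) and fingertip force is
  12 N per unit activation plus 0.05 N sensor noise, clipped to ±20 N;
- everything is reproducible bit-for-bit from one seed, and channels
  are conditionally independent given the activations, so experiments
  simulate only the channels they use.

The `"hard"` preset places the ring-extension map exactly on the
index-flexion map: the two movements then differ only through their
enslaved secondary activations. This reproduces the thresholding
decoder's failure mode (hotspot subsets collapse onto the shared blob
and the competition cannot separate the pair) while the spatial-filter
and discriminant decoders still separate them through the secondary
maps.

What passing tests on this generator do *not* show: robustness to
motor-unit-level signal structure, electrode-shift between sessions,
fatigue-induced spectral changes, or real enslaving nonlinearity. The
generator validates the decoding algebra and the relative behaviour of
the methods, not clinical performance.

## Frame-wise ground truth

The simulator labels a frame with a movement class when the
instantaneous target of the most-active finger is at least 10 % MVC
(the same threshold used for force-cycle detection), and rest
otherwise. This convention makes ramp edges genuinely ambiguous — a
window centred on a 12 %-MVC instant averages in sub-threshold samples
— and those knife-edge frames dominate the classifiers' error budget in
the evaluation experiments.

## Problem sizes of the shipped experiments

The test-suite and acceptance experiments use a scaled-down protocol:
2 repetitions per task–finger block (the full protocol uses 10), a
cohort of 5 synthetic subjects × 3 noise seeds evaluated at 48 and 8
electrodes, three concatenated training runs for the online-style
calibrations (a single run has only three contractions per movement,
too few to average over the spatial drift; the protocol explicitly
allows repeating contractions), and one closed-loop tracking run of 16
activations. With these sizes the offline cohort medians land at
CSP-PE nMSE ≈ 2.8 % / CA ≈ 90 % and LDA nMSE ≈ 1.2 % / CA ≈ 88–89 % at
48 electrodes, with CSP-PE's 8-electrode false-activation amplitude
(MAFA ≈ 0.23 %) below LDA's (≈ 0.35 %) — the min-fusion penalisation at
work. The LDA accuracy sits just below 90 % because its large empirical
rest prior demotes nearly all 10–20 % MVC frames to rest; this is a
property of the decoder under these study conditions, not a defect of
the implementation, and is reported as measured.

## Known limitations

- The CSP-PE fusion is a reconstruction (see above); other fusions
  (sums, soft-min) would change the proportional profile.
- The THR hotspot surrogate is deterministic; a human experimenter
  would adapt subset size and placement per subject.
- The force maps are linear; real force–EMG relations saturate near
  MVC.
- All evaluation is synthetic; numbers quoted here are medians of this
  package's own simulations, not measurements on human subjects.
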