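---
title: "Multiband non-linear complexity analysis of resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband non-linear complexity analysis of resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegcomplexity)
```

## The analysis in one paragraph

`eegcomplexity` implements a channel-resolved "brain complexity" pipeline
for awake resting-state EEG. Each subject's multichannel recording is
band-pass filtered (0.1--45 Hz, zero phase), downsampled to 256 Hz,
restricted to its first minute, and split into twelve 5 s windows. Every
window and channel is decomposed with a five-level biorthogonal-3.5
discrete wavelet filter bank into the five canonical sub-bands (delta
0.1--4 Hz, theta 4--8, alpha 8--16, beta 16--32, gamma 32--45 in the
octave convention), and ten non-linear features are estimated on each
band-limited series: correlation dimension (D2), largest Lyapunov
exponent (LLE), approximate entropy (ApEn), rescaled-range Hurst exponent
(H), detrended-fluctuation exponent (DFA), Higuchi and Katz fractal
dimensions, energy, and the Shannon and log-energy entropies. Features
are averaged over windows, z-scored per group pair, channel, band and
feature, and fed to a suite of sixteen fixed classifier presets under
leave-one-out cross-validation (LOOCV), giving one accuracy per
(channel, band, classifier). Band-wise mean and maximum accuracies over
channels summarize each group comparison, and the preset with the best
grand-mean accuracy is reported.

Because clinical EEG of this kind is rarely shareable, the package ships
a seeded synthetic cohort generator so that every stage of the pipeline
— including the end-to-end claim "an injected group difference at one
(channel, band) is detected there and nowhere else" — is testable from
code alone.

## Pipeline stages and their tunables

### Preprocessing

* **Filter**: zero-phase (forward–backward) windowed-sinc FIR band-pass,
  corners 0.1 and 45 Hz, order ≈ 1.5 × the sampling rate (≈ 2 Hz
  transition bands at 256 Hz). An FIR realization is the field's default
  for EEG (linear phase; no phase distortion of the non-linear features).
  A zero-phase IIR band-pass of modest order would leave ~30% of a 50 Hz
  tone, which is why the sharper FIR is used. The channel mean is
  removed before filtering (this kills the DC edge transient exactly)
  and again after.
* **Resampling**: integer-factor decimation with a zero-phase FIR
  anti-alias low-pass at 80% of the target Nyquist frequency; rational
  factors fall back to polyphase resampling. Upsampling is refused (the
  pipeline only ever downsamples, e.g. 2048 → 256 Hz).
* **Duration**: the first 60 s are kept: 15,360 samples at 256 Hz,
  which divides exactly into twelve 1280-sample windows. (A count of
  one extra boundary sample sometimes quoted for one minute of data is
  not used: exact divisibility makes the windowing unambiguous.)
* **Re-referencing** to named channels (e.g. linked mastoids) is an
  optional hook; synthetic data have no montage, so it defaults to a
  no-op.

### Sub-band decomposition

The five-level octave filter bank uses the published biorthogonal 3.5
filter pair with **periodized (circular) boundary handling**. Periodization
was chosen over symmetric extension because it gives exact perfect
reconstruction (the five band reconstructions plus the discarded D1
branch sum back to the input to ~1e-15) and bit-stable coefficient
lengths: a 1280-sample window yields exactly 40 level-5 approximation
coefficients. Features are computed on **single-branch reconstructions**,
not on the decimated coefficients: at level five only ~40 coefficients
remain per window, far too few for attractor-based estimators, and
reconstruction makes all bands length-comparable (1280 samples each).

The band-to-branch map at 256 Hz is fixed: gamma ← D2 (32--64 Hz, with
content above 45 Hz already removed by the low-pass), beta ← D3, alpha ←
D4, theta ← D5, delta ← A5.

Two properties of this (standard) wavelet deserve attention:

* The spline analysis high-pass of bior3.5 has a wide transition band.
  Tones at the *lower third* of an octave are split between neighbouring
  branches: a 40 Hz tone keeps only ~72% of its energy in the gamma
  branch (~25% leaks into beta), while tones near 1.5× the lower octave
  edge (6, 12, 24 Hz) keep ~87%. This is intrinsic to the filter pair —
  PyWavelets reproduces the same numbers — so analyses that need sharp
  band attribution should read neighbouring bands together.
* The periodized transform sees each window circularly. A tone that does
  not complete whole cycles within 5 s wraps with a discontinuity and
  splashes a few percent of its energy across branches. The synthetic
  generator therefore places its oscillation combs on the 0.2 Hz grid
  (whole cycles per window); real EEG has no such alignment and its
  branch energies carry this extra (small) variance.

### Feature estimators

All estimators are deterministic, pure functions of their input series.
Embedding parameters are estimated per series: the delay is the first
local minimum of the 16-bin histogram auto mutual information (no lower
value within the next five lags). Two degenerate shapes are handled
explicitly: a curve sitting wholly at the independence level (twice the
histogram bias, as for i.i.d. noise) gives delay 1, and a curve whose
region before the rise out of the minimum is flat relative to the
initial descent — the signature of a pure oscillation, whose binned AMI
plateaus — falls back to the first statistical zero crossing of the
autocorrelation (the quarter period). The dimension is the smallest m ≤ 10
with a false-nearest-neighbour fraction below 1% (ratio tolerance 15,
absolute tolerance two signal SDs, Theiler exclusion one delay); noisy
series that never settle return the cap with a warning.

* **D2** (Grassberger–Procaccia): correlation integral over a 20-point
  log-spaced radius grid between the 0.1th and 10th percentile of
  pairwise distances, Theiler window m·tau, slope over the automatically
  selected scaling region (longest sub-range with local slopes within
  15% of their median). The small-distance grid matters: at macroscopic
  radii the log-log curve flattens and a Lorenz attractor reads ~1.6
  instead of ~2.0. For speed the pair counts may subsample states
  (evenly strided; default cap 450 inside the pipeline, more when called
  directly); on short series (≤ 300 points, as in the oracle tests) no
  subsampling occurs.
* **LLE** (Rosenstein): nearest-neighbour log-divergence curve, fitted
  over its best linear region (same selector), slope divided by the
  sampling period. The commonly printed closed form of this estimator is not
  self-consistent; the standard average-log-divergence procedure it
  paraphrases is implemented instead.
* **ApEn**: m = 2, r = 0.2 × SD (the field defaults, stated explicitly since reports often omit
  them), Chebyshev distance, self-matches included — hence exactly
  scale-invariant.
* **H**: classical rescaled-range analysis over dyadic segment sizes
  16..N/2, slope of log mean R/S. Validated bias on fractional Gaussian
  noise at n = 4096 is ≤ 0.08 for H in {0.3, 0.5, 0.8}.
* **DFA**: order-1 detrending over twelve log-spaced scales 4..N/4;
  essentially unbiased on fGn and 0.50 / 1.50 on white / integrated
  noise.
* **Higuchi FD**: kmax = 8 with the standard curve-length normalization
  ((N−1)/(⌊a⌋k²)). Some printed forms of the curve length drop one factor
  of 1/k, which would shift a line to 0 and white noise to 1 instead of
  the canonical 1 and 2; the standard normalization is used.
* **Katz FD**: computed on (index, value) pairs with unit index step; an
  evenly spaced monotone line gives exactly 1.
* **Energy, ETs, ETL**: as printed, natural logarithms: EN = Σx²,
  ETs = −Σ x² log x², ETL = −Σ log x². Squared amplitudes below 1e-12
  contribute nothing to ETs and enter ETL through a floored logarithm.
  ETL's printed sign convention is nonstandard for an "entropy", but the
  features are discriminative statistics, not calibrated entropies, so
  the printed forms are kept.

Per-feature failures (constant windows, too few states, no scaling
region) are reported in a status column, never silently dropped; a
constant window has EN = 0 and ApEn = 0 by convention and all
geometry-based features flagged degenerate.

### Aggregation, normalization, classification

Window-level features are averaged per (subject, channel, band, feature)
over the windows whose status is usable, with the count recorded; empty
cells become missing and are group-mean imputed before classification.
Z-scoring pools both groups of a pair per (channel, band, feature) —
mean 0, SD 1 with the n−1 denominator; zero-variance cells are set to 0
with a warning. **Pooled z-scoring leaks distributional information into
LOOCV** (all subjects contribute to the statistics before any fold is
held out); it is nevertheless the default because it mirrors the
published order of operations. `runPair(..., normalization = "foldwise")`
recomputes the statistics from each training fold only, and a simulation
test asserts the leakage direction (pooled ≥ fold-safe on average under
the null).

The sixteen presets fix one published hyperparameter each (tree maximum
splits 4/20/100; SVM box constraints 3/3/4/3/3/1; KNN neighbour counts
1/10/100/10/10/10); everything else follows the conventions of the
commercial toolbox the suite mirrors: Gaussian kernel scales √P/4, √P,
4√P for P = 10 predictors; polynomial kernels (1 + x·y)^d; cosine and
Minkowski-3 KNN distances; squared-inverse-distance KNN weights; Gini
trees grown deep and pruned back to the split budget; unpenalized
logistic regression stabilized by a 1e-8 ridge so separation cannot
diverge. KNN vote ties break toward the first group label. Two presets
are structurally degenerate at this problem size and worth knowing
about: Coarse KNN (k = 100) exceeds any LOOCV training fold, so it
reduces to a majority vote that is always wrong under leave-one-out with
balanced groups; Fine Gaussian SVM's kernel scale is so small that all
kernel values vanish at typical z-scored distances and the fit predicts
the training majority. Both are kept — the suite is a fixed published
object — but neither can ever be selected as best classifier on data
like these.

LOOCV accuracy is the fraction of held-out subjects classified
correctly; it is invariant to subject order and deterministic. Note that
under the null, LOOCV accuracy is *not* centred exactly at 0.5: for
1-NN with balanced groups of n/2 the expected value is (n/2−1)/(n−1)
(5/11 ≈ 0.455 at n = 12 per side), because every training fold is
imbalanced against the held-out subject.

## The synthetic cohort: what it emulates and what it does not

Each channel is an independent sum over the five bands of

* a **narrow-band oscillation**: a fixed frequency comb near the band's
  effective centre (1.55× the lower octave edge, e.g. ~12.4 Hz for
  alpha) with randomized phases and a slow amplitude jitter; comb
  frequencies sit on the 0.2 Hz grid so analysis windows see whole
  cycles; and
* **band-confined fractional-Gaussian background noise**: spectral
  synthesis on the circulant-embedding grid of an fGn autocovariance
  (baseline Hurst exponent 0.6), brick-wall limited to the band, with
  deterministic spectral amplitudes and random phases, normalized so the
  realization's SD equals exactly the square root of the band's share of
  the unit-variance fGn spectrum.

Oscillation and noise are mixed 1:1 in amplitude at the baseline
exponent. Subjects are i.i.d. realizations; all between-subject
variability is phase noise. Pinning the spectral amplitudes and band
energies is a deliberate test-bed choice: it removes the amplitude
lottery that dominates real EEG between subjects, so that *injected
parameter shifts* — not realization luck — drive group differences, and
the null stays calibrated (a t-test sweep across all cells rejects at
the nominal 5% rate). Real EEG has enormous inter-subject amplitude
variance, volume conduction, artifacts and non-stationarity; passing
tests on this generator therefore demonstrates that the pipeline detects
band-local differences of the modelled kind, not that it would reach any
particular accuracy on clinical recordings.

Group effects act on the second group's generator parameters at chosen
(channel, band) cells:

* **hurst** adds its magnitude to the Hurst exponent of that band's
  noise. The component is *not* re-normalized, so the shift expresses
  the physical consequences of longer memory: the band's share of the
  fGn spectrum and the in-band tilt change (at the 0.6 baseline, +0.25
  raises the theta share by roughly three quarters). The baseline 0.6
  sits mid-range of the persistent exponents reported for awake EEG and
  keeps a +0.25 shift well inside (0, 1); note the share response is
  non-monotone in H (beyond ~0.85 the spectrum collapses onto
  frequencies below the delta band), so baselines near the top of the
  range would make effects degenerate.
* **energy** multiplies the band's energy by 1 + magnitude.
* **irregularity** moves the band's oscillation:noise variance balance
  toward noise, preserving total band energy.

One estimator-level caveat, verified empirically during design: the
rescaled-range H estimated *on a band-limited detail series* is
structurally pinned by the band geometry (partial sums of a 4--8 Hz
series saturate beyond one period), so a Hurst shift moves the measured
H at the targeted detail-band cell only slightly (~0.01); it is the
energy-share and tilt consequences that carry the detectable signature.
Only the delta (approximation) branch, which retains the low-frequency
scaling, tracks the generating exponent directly.

## Numerical choices and degenerate inputs

* Scaling regions (D2, LLE) are selected automatically as the longest
  low-curvature sub-range; manual region picking is not reproducible. If
  no region qualifies, the full-range slope is returned flagged
  `unreliable` (kept in window means, counted in statuses).
* Theiler exclusion (m·tau for D2/LLE, tau for FNN) suppresses trivial
  temporal neighbours; numerically coincident states (exact repeats of a
  periodic signal) are excluded from neighbour searches.
* H estimates outside [0, 1] are clipped and flagged.
* fGn synthesis uses exact Davies–Harte circulant embedding on a
  composite-size grid (fast FFT); a non-negative-definite failure (not
  observed for fGn) falls back to approximate spectral synthesis with a
  warning.
* Degenerate inputs error early with messages naming the offence:
  constant series for delay/H/DFA/Katz, attractors below the state
  minima (100 for D2, 200 for LLE), windows shorter than the recording,
  non-finite samples named by channel at load time.

## Problem sizes used by the test suite

The acceptance-style checks run, on one CPU, at deliberately scaled-down
study sizes chosen to finish in minutes while keeping every stage
honest: estimator recovery uses 50 fGn replicates at n = 4096; the
known-systems suite uses 5000 logistic-map points and 10,000 Lorenz
states; the end-to-end detection study uses two groups of 12 subjects,
8 channels and 60 s per subject (11,520 band series per cohort), with a
+0.25 Hurst shift injected at three channels in theta, plus an equally
sized null cohort. The published design this emulates used 32 channels
and four groups of 9--25 subjects.

## Known limitations

* Gamma-band attribution is soft (bior3.5 transition bands; see above).
* The generator produces no artifacts, no volume conduction, no
  cross-channel correlation and no inter-subject amplitude variability;
  it is a test bed, not a biophysical model.
* Pooled z-scoring (the published default) is optimistically biased;
  use `normalization = "foldwise"` for honest generalization estimates.
* Accuracies reported on real study data by the emulated design are not
  reproducible here: those recordings are not public, and no target
  value of this package refers to them.
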