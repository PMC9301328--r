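---
title: "Source-space TRF brain networks from hyperaligned EEG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space TRF brain networks from hyperaligned EEG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trfnet)
```

## The scientific problem

When people listen to continuous natural speech, low-frequency cortical
activity tracks the slow amplitude modulations of the acoustic signal (the
speech envelope).  Treating the listening brain as a linear time-invariant
system, the temporal response function (TRF) `r(tau)` maps the envelope
`s(t)` to the neural response of a region:

    x(t, ROI) = sum_tau r(tau, ROI) s(t - tau),    tau in [0, 800] ms.

Working in *source* space rather than electrode space lets the TRFs be
attributed to cortical regions, and correlating the TRF lag-courses between
regions yields a brain network whose community structure can be compared
between listening conditions (e.g. intelligible speech versus a
time-reversed control).  The obstacle is noise: each story is heard once, so
the usual trial averaging is unavailable.  The pipeline implemented here
substitutes *cross-subject* averaging, preceded by functional hyperalignment
so that individual differences in electrode placement do not cancel the
shared signal.

`trfnet` implements this chain end to end — multi-set CCA (MCCA)
hyperalignment, additive averaging, sLORETA source reconstruction, ROI
aggregation, encoder/decoder TRFs, signed TRF-correlation networks,
multi-scale community detection, and variation-of-information (VI) scale
selection — together with a seeded forward simulator that plants known
structure, so every stage is testable without any recorded data.

## The generative model of the simulator

`make_ground_truth()` + `simulate_study()` emulate the study design the
analysis assumes:

* **Stimuli.** Each trial has its own envelope: nonnegative band-limited
  (2–8 Hz) noise, the syllabic-rate band where speech envelopes carry most
  of their power (`make_envelope()`).  For real audio,
  `extract_envelope()` implements the standard gammatone filterbank →
  power-law compression (exponent 0.6) → band average → low-pass →
  decimation chain.
* **Responses.** Each of 68 ROIs (a Desikan–Killiany-sized parcellation)
  responds with a damped-oscillation kernel on the 0–800 ms lag grid.
  Kernels are organized into planted communities: ROIs in a community share
  a template (community-specific latency in 60–380 ms, frequency 3–7 Hz,
  polarity) plus ~15% ROI-specific jitter, so within-community kernel
  correlation exceeds between-community correlation — the property the
  network stage is supposed to detect.  Condition B either re-draws labels
  and templates (`condition_b = "redraw"`, the natural/reversed-speech
  analog) or differs from A only inside one lag window
  (`condition_b = "windowed"`, used for window-specificity analyses).
* **Forward model.** 500 sources on a 2-D sheet project to 122 channels
  (a 128-electrode montage minus non-EEG channels) through a smooth random
  lead field: each channel's gain map is a Gaussian-smoothed random field
  (radius 1.5 grid units), singular values clipped to condition number
  ≤ 50.  Smoothness makes inverse leakage *local*; communities are
  contiguous ROI blocks, so leakage predominantly mixes kernels of the same
  community.  The radius matters: much broader smoothing makes neighboring
  ROIs inherently indistinguishable and region-level recovery meaningless.
* **Subject differences.** Each subject's EEG passes through an orthogonal
  channel mixing that rotates every plane of a random per-subject basis by
  the `misalignment` angle (default 1.2 rad), emulating the combined
  cap-placement and functional-anatomy differences between subjects while
  preserving signal power so SNR bookkeeping stays exact.  The angle is
  deliberately consequential: the naive cross-subject average attenuates the
  shared signal by roughly `cos(misalignment)` per plane, which is the
  problem hyperalignment exists to fix.  (An earlier parameterization that
  scaled a random skew matrix to a target operator norm made only the worst
  plane reach the nominal angle; the parameter had almost no effect and was
  replaced.)
* **Noise.** Two independent per-subject terms, split by `noise_mix`
  (default 3/4 vs 1/4): *background source activity* — 1/f-plus-white noise
  at every source, projected through the same lead field and mixing as the
  signal, so pooling channels cannot average it away but cross-subject
  averaging can (the premise behind the whole design) — and spatially white
  *sensor noise* per channel.  `snr_db` is the variance ratio of the
  stimulus-locked signal to the total noise at the sensors, calibrated
  exactly per subject-trial; the default −15 dB puts single-trial envelope
  decoding near the upper end of the published empirical range (sensor
  noise alone, however extreme, cannot do this: it is spatially white and a
  122-channel decoder averages it away).
* **Scale.** 21 subjects, 48 trials (24 per condition), 250 Hz — the study
  dimensions the analysis is designed for.  Trial duration (6 s) and source
  count (500) are desk-scale package choices: full-length stories at this
  subject/trial count would be a ~40 GB array with no change in what the
  tests can demonstrate.

What the simulator deliberately does **not** model: cortical geometry and
volume-conduction physics, artifacts (blinks, EMG), inter-subject response
*shape* variability, and non-stimulus-locked brain dynamics.  Passing tests
therefore demonstrate correctness of the estimators under the stated
generative assumptions, not performance on real recordings.

## Hyperalignment (MCCA) and additive averaging

For subjects `i = 1..I` with centered data `X_i`, MCCA maximizes the summed
between-set correlation

    rho = (1/(N-1)) * sum_{i != j} w_i' V_ij w_j / sum_i w_i' V_ii w_i,

which reduces to the generalized eigenproblem `B w = lambda R w`, with `B`
holding the between-set covariance blocks (zero diagonal) and `R` the
block-diagonal within-set covariances.  We take the normalizer `N = I`, the
only reading under which identical datasets give exactly `rho = 1` (and the
bound `rho <= 1` holds for the leading components); `rho = lambda/(I-1)`.
The solver whitens with the block-diagonal Cholesky factor of `R`
(ridge-stabilized by `1e-6` of each block's mean diagonal) and solves a
symmetric eigenproblem, which keeps the generalized eigen-residual below
1e−8 for the retained components.

Denoising truncates each subject to its leading `K` canonical components
and averages across subjects.  Two averaging spaces are implemented, and
which one is used matters more than any other choice in this module:

* *Electrode space*: each subject is back-projected through the
  pseudoinverse of its own truncated projection, then averaged.  This is
  simple, but the average carries exactly the same mean-rotation
  attenuation as the naive average — per-subject back-projection cannot
  undo a rotation that happens before averaging — so it can only beat naive
  averaging through noise-subspace truncation, a fragile margin.
* *Component space* (the pipeline default): canonical scores, which are
  aligned across subjects by construction, are averaged and back-projected
  to the montage through the pseudoinverse of the subject-averaged
  projection.  The shared signal adds coherently whatever the misalignment;
  at the default study conditions this is what produces the
  hyperaligned > naive > single-trial ordering.

Other open choices were resolved as follows:

* **Truncation `K`.** "Components carrying 90% of the eigenvalue mass"
  over-retains on realistic noise spectra — once `K` reaches the per-subject
  channel count the back-projection is the identity and nothing is denoised.
  The default is therefore `min(90%-mass K, floor(channels/2))`,
  overridable via `n_components`.
* **Fit scope.** MCCA is fit once on the trial-concatenated data (per-trial
  fits would re-estimate electrode geometry per trial, which is not the
  model).  For full-size studies `fit_mcca_eeg()` assembles the covariance
  blocks from a decimated time grid (≤ 20,000 samples/subject): 250 Hz EEG
  is heavily oversampled relative to its 1–40 Hz content, so second-order
  statistics are unchanged while memory stays flat.

## Source reconstruction (sLORETA) and ROI series

The inverse operator is the minimum-norm kernel `T = L'(LL' + aI)^{-1}` with
`a` expressed as a fraction (default 0.05) of the mean eigenvalue of `LL'`,
standardized per source by the diagonal of the resolution matrix `TL`
(fixed-orientation sources, so the standardization factors are scalars).
Standardization gives the method its defining property — exactly zero
localization error for noiseless point sources, which follows from the
Cauchy–Schwarz inequality in the `TL` inner product and holds at any
regularization level; the test suite checks 20/20 random sources.  ROI time
series are plain means over member sources (a sign-flip option exists but
is off: the aggregation the pipeline models is a plain average).

## TRF estimation

Encoders are per-ROI ridge regressions of the ROI series on the lagged
envelope (0–800 ms at the 4 ms sampling step).  Because the envelope is
band-limited, the lagged design is ill-conditioned: unregularized solutions
put large noise into the unidentifiable directions.  The pipeline default
ridge is 0.1 × the mean diagonal of the design Gram matrix, the value at
which held-out response prediction plateaus — a data-driven criterion that
does not look at the planted kernels.

The decoder is one multivariate ridge regression reconstructing the
envelope from all ROIs jointly.  Since the neural response *lags* the
stimulus, the decoder consumes anti-causal lags `x(t + tau)` (the standard
backward-model convention); the lag span is still 0–800 ms, on a 40 ms grid
in the pipeline (68 ROIs × 201 lags would be a 13,668-column design with no
accuracy benefit at this envelope bandwidth).  `loo_crossval()` implements
leave-one-out evaluation with per-trial Gram accumulation — each fold is a
single regularized solve — choosing the ridge per fold from a
trace-normalized grid by mean reconstruction correlation over inner folds
of the training trials.  Reported accuracies are Fisher-z transformed
(`atanh`) before averaging.

## Networks, signed communities, and scale selection

Per-trial networks are Pearson correlations between ROI TRF lag-courses
(2,278 edges for 68 ROIs); condition-level networks are Fisher-z means of
the per-trial matrices.  `threshold_density()` keeps the `ceiling(t * E)`
largest-|weight| edges with signs retained (ties broken lexicographically,
so thresholding is deterministic), and `detect_communities()` maximizes the
asymmetric signed modularity

    Q = Q+ - (v- / (v+ + v-)) Q-

by Louvain optimization on the signed modularity matrix (resolution
γ = 1), with 100 seeded restarts and a guarantee of never returning worse
than the single-community baseline.  Positive within-community weight is
rewarded at full strength; negative within-community weight is penalized in
proportion to its share of total weight.

The density grid 0.01–0.50 (step 0.01) is scanned; partition stability is
measured by the VI between partitions at consecutive densities (in nats,
computed in a form whose terms are individually nonnegative, so identical
partitions give exactly zero).  The selection rule formalizes the informal
"all conditions satisfied" criterion: among densities whose
condition-separability F1 is within 0.02 of the maximum, pick the one
minimizing VI; ties go to the smallest (sparsest) density.  The
per-density F1 clusters the thresholded per-trial networks of both
conditions into two groups and scores them against the condition labels.

## Separability scoring

Networks are vectorized (row-major upper triangle), embedded in 2-D, and
clustered by k-means (k = 2, 1,000 random-initialization repetitions).  F1
uses best-permutation matching of clusters to conditions, whose chance
level on balanced 24+24 designs sits *above* 0.5 (empirically ≈ 0.6–0.7);
the suite calibrates it by simulation rather than assuming 0.5.  The
default embedding is PCA — deterministic and sufficient for these feature
matrices; an exact (dense) t-SNE implementation (perplexity 10, seeded) and
classical MDS are selectable alternatives.  TRF window clustering applies
the same machinery to per-ROI mean TRF amplitudes in the four windows
0–150, 150–300, 300–450, 450–600 ms; "amplitude" is the signed mean of the
kernel in the window.

## Numerical and degenerate-input conventions

* All stochastic operations take explicit seeds; child seeds are derived
  deterministically from the master seed, and identical configurations give
  bit-identical pipeline reports (`report_digest()`).
* Zero-variance envelopes are fit failures; zero-variance TRF rows get
  missing correlations (error above 10% of rows); constant test envelopes
  in cross-validation are recorded as missing with a warning.
* Paired window statistics: identical sets return `t = 0, d = 0`; a nonzero
  constant shift with zero within-pair variance is reported as a
  degenerate-variance error rather than an infinite t.
* `edge_count`, thresholding and vectorization validate their combinatorial
  contracts (e.g. a 68-node network has exactly 2,278 edges; density 0.14
  retains exactly 319).

## Problem sizes used by the tests and the acceptance script

The shipped verification runs use the default study above (21 subjects ×
48 × 6 s × 122 channels at 250 Hz; ~1.5 GB of raw simulated data), one
auxiliary study at 10 dB SNR with the window-confined condition difference
(kernel recovery and window specificity share it), and small closed-form
fixtures for the oracle-equivalence checks.  On one CPU the full pipeline
run takes on the order of ten minutes; the simulator scales linearly in
subjects, trials, duration and channels if larger experiments are wanted.

A calibration note on what the default study is for: it is a *validation
testbed* at the study conditions the analysis presupposes — single-trial
estimation too noisy to be useful, cross-subject averaging strong, and
misalignment consequential — not a forecast of real-data effect sizes.
With background noise at the fully literature-matched level (around −25 dB
stimulus-locked SNR, giving single-trial decoding r ≈ 0.15) the 6-s
desk-scale trials leave too little data for any pathway to show its
properties; the real study's ~60-s stories carry ten times the samples per
trial.  The default −15 dB restores the product of SNR and trial length to
a comparable information budget.

## Known limitations

* The forward model is a statistical stand-in, not a head model: no
  realistic geometry, conductivity or depth effects, so localization
  results say nothing about anatomical accuracy on real EEG.
* Region-level kernel recovery is bounded by inverse-solution leakage even
  in the noiseless limit (~0.97 mean correlation under the default
  geometry); boundary ROIs between communities recover worst.
* The F1 chance level depends on the cluster-to-label matching
  convention; best-permutation matching is used throughout, and its chance
  band is calibrated, not assumed.
* A condition difference planted in one lag window smears into neighboring
  windows by roughly the envelope autocorrelation width (~100 ms): the
  band-limited stimulus makes nearby lags statistically interchangeable, so
  window-specificity analyses identify the planted window as (joint)
  maximal rather than uniquely so at high SNR.
* Signed-modularity Louvain is greedy: restarts mitigate but do not
  eliminate local optima; on weak structure different seeds can return
  different partitions (the VI curve makes this visible).
* In a fully linear, stationary simulator a supervised ridge decoder is
  close to optimal on whatever data it is given, so unsupervised
  truncation before decoding cannot add information — the hyperalignment
  gain appears only through aligned averaging under consequential
  misalignment, and the naive-vs-hyperaligned decoding margin is the
  smallest contrast in the pipeline, as it is in real data.
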