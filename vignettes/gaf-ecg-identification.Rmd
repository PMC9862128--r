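---
title: "Closed-set ECG identification with Gramian Angular Field images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-set ECG identification with Gramian Angular Field images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gafid)
```

## The problem

Electrocardiograms carry a per-person morphological signature: the relative
amplitudes, widths and timings of the P, Q, R, S and T waves are stable
within a person and variable between people. A closed-set identification
system exploits this: given a few seconds of single-lead ECG from one of N
enrolled users, decide which user produced it. `gafid` implements one
complete, non-fiducial pipeline for this task — no R-peak detection or
landmark extraction anywhere:

1. **Cleaning** — DC removal, zero-phase band-pass filtering;
2. **Windowing** — fixed W-second windows, no beat alignment;
3. **Encoding** — each window becomes a Gramian Angular Summation Field
   (GASF) image;
4. **Classification** — a VGG-style convolutional network with a softmax
   head over the N enrolled users;
5. **Scoring** — accuracy, confusion matrix, FAR, FRR and their ratio K.

A synthetic cohort generator stands in for clinical archives so that the
entire pipeline is runnable, testable and exactly reproducible offline.

## The GASF encoding

For a window $X = \{x_1,\dots,x_n\}$ the encoder first rescales into
$[-1, 1]$:

$$\tilde x_i = \frac{(x_i - \max X) + (x_i - \min X)}{\max X - \min X},$$

then maps values to angles and timestamps to radii,

$$\phi_i = \arccos(\tilde x_i), \qquad r_i = t_i / N_{\mathrm{reg}},$$

and forms the matrix of pairwise angular sums

$$G_{ij} = \cos(\phi_i + \phi_j)
        = \tilde x_i \tilde x_j - \sqrt{1-\tilde x_i^2}\sqrt{1-\tilde x_j^2}.$$

$G$ is symmetric, has entries in $[-1,1]$ and diagonal
$G_{ii} = 2\tilde x_i^2 - 1$. Unlike a spectrogram it preserves temporal
structure explicitly: row $i$ is the interaction of sample $i$ with every
other sample in order. The cost is quadratic growth — a $1\times n$ series
becomes an $n\times n$ image — so a Piecewise Aggregate Approximation
(PAA) reduces the window to $m$ frame means first (`paa()`); frames
partition the window and weight boundary samples fractionally, so the
global mean is preserved for every $(n, m)$.

Two numerical subtleties are worth recording:

* **Clamping.** Rescaled values can spill outside $[-1,1]$ by a few ulp;
  `toPolar()` clamps spill up to $10^{-12}$ and rejects anything larger.
* **Recovery and the sign bit.** The series is recoverable from the main
  diagonal via $|\tilde x_i| = \sqrt{(G_{ii}+1)/2}$. In *unit* mode
  ($[0,1]$ rescale) this is the exact series, unconditionally. In the
  printed *symmetric* mode the diagonal only fixes magnitudes, and $G$
  itself is invariant under global negation of the series, so no algorithm
  can recover the sign pattern from $G$ alone. `gasf()` therefore stores
  one bit of encoding metadata — the sign of the reference element (the
  temporally first largest-magnitude value, for which $G_{rj} = \tilde x_r
  \tilde x_j$ exactly) — and `recoverSeries()` resolves every other sign
  against that row. With the bit the round trip is exact to $10^{-9}$ in
  both modes; without it, exact up to a global flip.

## Cleaning defaults

`preprocessConfig()` defaults to a 0.67–45 Hz pass band, order-4
Butterworth, window W = 5 s, no overlap:

* **0.67 Hz high-pass** sits above respiratory baseline wander (< ~0.7 Hz)
  and below the slowest P–T content of interest.
* **45 Hz low-pass** removes 50/60 Hz powerline interference and broadband
  sensor noise while keeping QRS energy.
* The band-pass is realised as cascaded high-pass and low-pass sections —
  at a normalized low edge of ~0.01 a single band-pass polynomial design
  is ill-conditioned — and each section is applied forward-backward
  (`signal::filtfilt`), so the net filter has zero phase and wave timing
  is undistorted. At 128 Hz sampling the measured zero-phase amplitude
  response is ≥ 20 dB down at both 0.2 Hz and 50 Hz relative to 10 Hz
  (the test suite asserts this against the designed filter's response).
* **W = 5 s** covers several heartbeats at any plausible heart rate and is
  a realistic authentication latency. Windows are *not* beat-aligned; the
  classifier must absorb beat phase (see augmentation below).

## The synthetic cohort generator

`generateCohort()` emulates the structure the classifier needs from real
recordings, without claiming to model any real population:

* **Identity**: each subject is a draw of PQRST wave phases, amplitudes
  and widths around the classical dynamical-ECG-model means
  ($\theta$ = −1.22, −0.26, 0, 0.26, 1.75 rad; $a$ = 0.12, −0.5, 1.5,
  −0.75, 0.35; $b$ = 0.25, 0.10, 0.10, 0.10, 0.40 rad). Between-subject
  standard deviations default to 15% of each mean magnitude, with a 0.05
  rad floor for phases (the R wave's mean phase is 0, so a pure
  percentage would freeze it).
* **Within-subject nuisance**: per-beat multiplicative jitter (3%) on
  amplitudes and widths, beat-to-beat RR variability (subject-level sd ~3
  bpm), resting heart rates truncated to 50–100 bpm.
* **Noise**: sinusoidal baseline wander (0.3 Hz, amplitude 0.2), 50 Hz
  powerline interference (amplitude 0.05) and white sensor noise
  (sd 0.03), against an R-wave amplitude of ~1.5.
* **Activities** scale heart rate and noise monotonically — resting
  (1.0/1.0/1.0), math (1.15/1.2/1.0), walking (1.5/2.0/1.5), running
  (2.0/3.5/2.0), handbike (1.6/3.0/1.8) for (HR, motion noise, wander).

The 15%-between / 3%-within split enforces the identifiability condition
(between > within, checked at configuration time) and was fixed once as a
plausible morphological effect size; it is a modelling choice, not an
estimate of any real cohort. What the generator deliberately omits:
respiratory sinus arrhythmia, intra-beat phase warping, pathological
rhythms, electrode motion artefacts and sensor dropout. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's machinery is
correct and that it can exploit a morphology-borne identity signal — not
that any particular accuracy will transfer to a real population.

Reproducibility: one cohort seed fans out into per-(subject, activity)
substreams by stable hashing of the indices, so any single recording can
be regenerated in isolation, independent of generation order.

```{r cohort, eval = FALSE}
pop <- populationConfig(nSubjects = 10, seed = 1)
recs <- generateCohort(pop, "resting", durationPerActivity = 120)
ds <- cohortToGAF(recs, paaSize = 64)
```

## The classifier

`modelConfig()` describes a tuned-VGG19-style network: a stem of two
conv–conv–max-pool blocks, a core of five 3×3 convolutions (ReLU), max
pooling, global average pooling, dropout 25%, a ReLU dense layer, dropout
10%, and a softmax layer over the N users. Training minimises softmax
cross-entropy with Adam under a deterministic step decay (the learning
rate halves every 50 epochs — a validation-triggered decay was rejected
because the augmented validation loss is noisy enough to collapse the
rate during transient plateaus) and early-stops on validation loss with
the best-epoch weights restored. The network, its backpropagation and Adam are
implemented natively in Rcpp/Armadillo; a minibatch moves through each
layer as a single im2col + GEMM. Arithmetic inside the trainer is single
precision — the norm for network training, and about twice the CPU
throughput of doubles — while weights and probabilities cross the R
boundary as doubles (softmax rows are renormalised in double precision).
Every source of randomness (initialisation, shuffling, dropout,
augmentation) derives from one seeded generator, so training is
bit-reproducible on a single machine.

Two profiles:

| | full | desk |
|---|---|---|
| input | 128×128, 3-channel | 64×64, 1-channel |
| stem filters | 64 / 128 | 8 / 16 |
| core | 5 × conv-512 | 5 × conv-32 |
| dense | 256 | 64 |
| Adam LR | 1e-5 | 1e-3 |
| augmentation | off | circular shift |

The *full* profile mirrors the reference architecture (~10^7 parameters;
`numParameters()` reports the exact count) and accepts externally supplied
stem weights (`usePretrainedStem`); nothing is downloaded. The *desk*
profile preserves the architecture's shape at a cost of CPU-minutes and is
what every packaged experiment and test uses.

**Circular-shift augmentation.** Windows are not beat-aligned, so beat
phase is the dominant within-class nuisance, and a few dozen windows per
subject cannot cover it. A circular shift of the encoded window by $s$
samples permutes the GASF's rows and columns by the same rotation
($G_{ij}$ depends only on the value pair), so the augmentation is applied
directly to training images — exact, label-preserving, interpolation-free
and seeded. It is a training-regime choice of the desk profile, off by
default in the full profile.

## Evaluation semantics

In the closed-set setting every probe belongs to an enrolled user, and the
paper-style error metrics are defined as:

* **FRR** — fraction of genuine probes not accepted as their own identity
  (with pure argmax this equals 1 − accuracy);
* **FAR** — macro-average over identities $i$ of the rate at which probes
  of *other* users are labelled $i$;
* **K** — the ratio FRR/FAR, reported as `NA` when FAR = 0.

For balanced classes these definitions are linked exactly:
FAR = FRR/(C−1), hence K = C−1 — with 10 enrolled users, K = 9 whenever
any errors occur at all. This identity is asserted by brute-force
enumeration in the test suite, and it explains why a 10-user closed-set
experiment reports K ≈ 9 regardless of its accuracy. An optional rejection
threshold $\tau$ on the top softmax probability turns unsure predictions
into rejections (counted in FRR, excluded from false accepts); FRR is then
non-decreasing and FAR non-increasing in $\tau$. Argmax ties break toward
the lowest class index. The default is pure argmax ($\tau$ = none).

`splitDataset()` partitions stratified by subject (largest-remainder
apportionment per class, every split guaranteed at least one image, seeded
shuffling); 80/10/10 is the default, two-way splits are supported.

## Packaged experiment sizes

The end-to-end experiments used by the acceptance script and tests are
sized for a single CPU: 10 subjects × 120 s of signal per activity at
128 Hz, W = 5 s (24 windows per recording), PAA 64, desk profile with
batch 16 and at most 150 epochs (early stopping patience 25). The resting
experiment trains on ~190 images; the four-activity experiment (resting,
math, walking, running — a sedentary-to-exercise spread) on ~770. These
sizes are the package's chosen demonstration scale; the pipeline itself
has no scale constants baked in.

## Known limitations

* The symmetric-mode diagonal-recovery claim requires the stored sign bit
  (see above); unit mode needs nothing.
* FAR/FRR definitions for closed-set identification are not standardised;
  the macro-average reading implemented here reproduces the K = C−1
  structure but other readings exist.
* The desk profile's accuracy on synthetic cohorts says nothing
  quantitative about real ECG archives (see the generator's omissions).
* Single lead only; no open-set enrolment, verification-mode ROC/EER,
  template aging, or artefact rejection.
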