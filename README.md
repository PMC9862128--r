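# gafid — ECG biometric identification with Gramian Angular Field images

Single-lead ECG recordings carry a per-person morphological signature: the
relative amplitudes, widths and timings of the P, Q, R, S and T waves.
`gafid` implements a complete closed-set identification pipeline that
exploits it without any fiducial-point detection:

raw ECG → cleaning (DC removal + zero-phase 0.67–45 Hz band-pass) →
fixed 5 s windows → **Gramian Angular Summation Field** images →
VGG-style convolutional classifier → identification metrics
(accuracy, confusion matrix, FAR, FRR, K).

The GASF encodes a window X = {x₁…xₙ} by rescaling to [−1, 1],

    x̃ᵢ = ((xᵢ − max X) + (xᵢ − min X)) / (max X − min X),

mapping values to angles φᵢ = arccos(x̃ᵢ), and forming the matrix of
pairwise angular sums

    G_ij = cos(φᵢ + φⱼ) = x̃ᵢx̃ⱼ − √(1−x̃ᵢ²)·√(1−x̃ⱼ²),

optionally after Piecewise Aggregate Approximation (PAA) to control the
image size. G is symmetric, bounded in [−1, 1], has diagonal
G_ii = 2x̃ᵢ² − 1, and — unlike spectral encodings — keeps temporal
structure explicit, which is what the convolutional classifier consumes.

Because real ECG archives cannot be bundled, the package includes a
first-class synthetic cohort generator (sum-of-Gaussians PQRST beat model
with per-subject morphology, heart-rate variability, activity profiles,
baseline wander, powerline interference and sensor noise), so the whole
pipeline runs, trains and is tested end-to-end offline and bit-reproducibly.
The classifier itself — convolutions, pooling, dropout, Adam, early
stopping — is implemented natively in Rcpp/Armadillo.

## Worked example

Ten synthetic subjects, two minutes of resting ECG each, 5-second windows
encoded as 64×64 GASF images, desk-scale model:

```r
library(gafid)

pop  <- populationConfig(nSubjects = 10, seed = 3)
recs <- generateCohort(pop, "resting", durationPerActivity = 120)
ds   <- cohortToGAF(recs, paaSize = 64)
ds
#> GAFDataset: 240 images of 64 x 64, 10 subject(s)
#>   meta: windowSeconds, paaSize, rescaleMode, source

sp  <- splitDataset(ds, c(0.8, 0.1, 0.1), seed = 3)
cfg <- modelConfig("desk", numClasses = 10, batchSize = 16,
                   maxEpochs = 150, patience = 25, seed = 3)
net <- trainModel(buildModel(cfg), sp$train, sp$val, seed = 3)
report <- evaluateModel(net, sp$test)
report
#> EvalReport: 10 classes, 20 probes
#>   accuracy 0.8500  FRR 0.15000  FAR 0.01667  K 9.00
```

Reading the numbers: `accuracy` is the fraction of 5-second probes
assigned to the right enrolled user (17 of the 20 held-out windows here);
`FRR` (false rejection rate) is its complement under pure argmax; `FAR`
(false acceptance rate) is the macro-averaged rate at which other users'
probes are accepted as a given identity; and `K = FRR/FAR` summarises the
error balance — for balanced classes K equals C − 1 exactly (9 for ten
users), so false accepts are nine times rarer than false rejects. Repeat
runs with other seeds land in the 0.75–1.00 accuracy range at this small
demonstration scale. `confusionMatrix()`,
`identificationMetrics()` and a rejection-threshold mode are available
separately, and `trainingHistory(net)` holds the per-epoch curves.

A thin command-line front end over the same functions lives at
`inst/cli/gafid.R` (subcommands `simulate`, `preprocess`, `train`,
`evaluate`).

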