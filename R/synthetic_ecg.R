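#' @name synthetic-ecg
#' @title Synthetic multi-subject ECG cohorts
#'
#' @description
#' The generator emulates the structure an identification pipeline needs
#' from real single-lead data: a stable per-subject PQRST morphology (the
#' identity signal), between-subject variation exceeding within-subject
#' beat-to-beat jitter, heart-rate variability, activity-dependent heart
#' rate and noise, baseline wander, powerline interference and broadband
#' sensor noise. Each beat is the sum-of-Gaussians model
#' \eqn{z(\theta) = \sum_k a_k \exp(-(\theta-\theta_k)^2/(2 b_k^2))} over a
#' phase sweep \eqn{\theta \in [-\pi, \pi)} spanning one RR interval.
NULL

# restore the caller's RNG state after seeded draws
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

# stable per-(subject, activity) substream: one cohort seed fans out into
# independent small-integer seeds, independent of generation order
.deriveSeed <- function(seed, a = 0L, b = 0L) {
  as.integer((as.numeric(seed) %% 2147483647 * 1009 +
              as.numeric(a) * 1013904223 +
              as.numeric(b) * 69069 + 1) %% 2147483647)
}

#' Noise model configuration
#'
#' @param wanderFreq baseline-wander (respiratory) frequency in Hz; must be
#'   below ~0.7 Hz where the cleaning high-pass starts.
#' @param wanderAmp wander amplitude in signal units.
#' @param powerlineFreq mains frequency in Hz (50 in Europe).
#' @param powerlineAmp powerline amplitude in signal units.
#' @param whiteSD broadband sensor-noise standard deviation.
#' @return a named list of class `"NoiseConfig"`.
#' @export
noiseConfig <- function(wanderFreq = 0.3, wanderAmp = 0.2,
                        powerlineFreq = 50, powerlineAmp = 0.05,
                        whiteSD = 0.03) {
  if (wanderFreq <= 0 || powerlineFreq <= 0)
    stop("noise frequencies must be positive")
  if (wanderAmp < 0 || powerlineAmp < 0 || whiteSD < 0)
    stop("noise amplitudes must be non-negative")
  structure(list(wanderFreq = wanderFreq, wanderAmp = wanderAmp,
                 powerlineFreq = powerlineFreq, powerlineAmp = powerlineAmp,
                 whiteSD = whiteSD), class = "NoiseConfig")
}

#' Activity profiles
#'
#' Each activity scales the subject's mean heart rate, the broadband motion
#' noise and the baseline-wander amplitude, mimicking the monotone
#' escalation from sitting quietly to treadmill running.
#'
#' @param names activities to return (default: all five).
#' @return named list of profiles, each a list with `name`, `hrScale`,
#'   `motionNoiseScale`, `baselineWanderScale`.
#' @examples
#' activityProfiles(c("resting", "running"))
#' @export
activityProfiles <- function(names = c("resting", "math", "walking",
                                       "running", "handbike")) {
  defaults <- list(
    resting  = list(hrScale = 1.0,  motionNoiseScale = 1.0, baselineWanderScale = 1.0),
    math     = list(hrScale = 1.15, motionNoiseScale = 1.2, baselineWanderScale = 1.0),
    walking  = list(hrScale = 1.5,  motionNoiseScale = 2.0, baselineWanderScale = 1.5),
    running  = list(hrScale = 2.0,  motionNoiseScale = 3.5, baselineWanderScale = 2.0),
    handbike = list(hrScale = 1.6,  motionNoiseScale = 3.0, baselineWanderScale = 1.8)
  )
  bad <- setdiff(names, names(defaults))
  if (length(bad)) stop("unknown activity: ", paste(bad, collapse = ", "))
  out <- lapply(names, function(nm) {
    p <- defaults[[nm]]
    p$name <- nm
    structure(p, class = "ActivityProfile")
  })
  names(out) <- names
  out
}

#' Population configuration for synthetic cohorts
#'
#' Population-level means and dispersions of the per-subject beat
#' morphology. The defaults are the classical dynamical-ECG-model wave
#' parameters; between-subject standard deviations default to 15% of each
#' mean magnitude (with a 0.05 rad floor for wave phases, whose R-wave mean
#' is 0), and within-subject per-beat jitter to 3% — a population in which
#' identity is carried by morphology and comfortably exceeds beat-to-beat
#' variation (the identifiability condition betweenSDFrac > withinJitter is
#' enforced).
#'
#' @param nSubjects number of subjects.
#' @param thetaMeans,ampMeans,widthMeans length-5 PQRST wave parameters.
#' @param betweenSDFrac between-subject sd as a fraction of |mean|.
#' @param angleSDFloor absolute sd floor for wave phases (radians).
#' @param withinJitter within-subject per-beat relative jitter sd.
#' @param hrMean,hrBetweenSD population mean heart rate (bpm) and its
#'   between-subject sd; subjects are truncated to [50, 100] bpm at rest.
#' @param hrSDMean,hrSDBetweenSD population distribution of each subject's
#'   beat-to-beat heart-rate sd (bpm).
#' @param noise a [noiseConfig()].
#' @param samplingRate Hz.
#' @param seed cohort seed.
#' @return a named list of class `"PopulationConfig"`.
#' @export
populationConfig <- function(nSubjects = 10L,
                             thetaMeans = c(-1.22, -0.26, 0, 0.26, 1.75),
                             ampMeans = c(0.12, -0.5, 1.5, -0.75, 0.35),
                             widthMeans = c(0.25, 0.10, 0.10, 0.10, 0.40),
                             betweenSDFrac = 0.15, angleSDFloor = 0.05,
                             withinJitter = 0.03,
                             hrMean = 65, hrBetweenSD = 8,
                             hrSDMean = 3, hrSDBetweenSD = 1,
                             noise = noiseConfig(), samplingRate = 128,
                             seed = 1L) {
  if (nSubjects < 1L) stop("nSubjects must be positive")
  if (betweenSDFrac <= withinJitter)
    stop("identifiability requires between-subject sd fraction (",
         betweenSDFrac, ") > within-subject jitter (", withinJitter, ")")
  if (samplingRate < 100)
    stop("samplingRate must be at least 100 Hz to resolve QRS morphology")
  stopifnot(length(thetaMeans) == 5L, length(ampMeans) == 5L,
            length(widthMeans) == 5L)
  structure(list(nSubjects = as.integer(nSubjects), thetaMeans = thetaMeans,
                 ampMeans = ampMeans, widthMeans = widthMeans,
                 betweenSDFrac = betweenSDFrac, angleSDFloor = angleSDFloor,
                 withinJitter = withinJitter, hrMean = hrMean,
                 hrBetweenSD = hrBetweenSD, hrSDMean = hrSDMean,
                 hrSDBetweenSD = hrSDBetweenSD, noise = noise,
                 samplingRate = samplingRate, seed = as.integer(seed)),
            class = "PopulationConfig")
}

#' Draw one synthetic subject from a population
#'
#' Morphology parameters are drawn from independent normals around the
#' population means (truncated to the [SubjectParams-class] invariants:
#' ordered wave phases, positive widths, resting heart rate in [50, 100]
#' bpm). Deterministic given `(seed, index)`.
#'
#' @param population a [populationConfig()].
#' @param index subject index (drives the per-subject substream).
#' @param seed cohort seed; defaults to the population's.
#' @return a [SubjectParams-class].
#' @export
sampleSubject <- function(population, index = 1L, seed = population$seed) {
  stopifnot(inherits(population, "PopulationConfig"))
  p <- population
  .withSeed(.deriveSeed(seed, index, 0L), {
    thetaSD <- pmax(p$betweenSDFrac * abs(p$thetaMeans), p$angleSDFloor)
    thetas <- NULL
    for (try in 1:100) {
      cand <- stats::rnorm(5, p$thetaMeans, thetaSD)
      if (all(diff(cand) > 0) && all(cand > -pi) && all(cand < pi)) {
        thetas <- cand
        break
      }
    }
    if (is.null(thetas))
      stop("could not draw ordered wave phases; population sds too wide")
    amps <- stats::rnorm(5, p$ampMeans, p$betweenSDFrac * abs(p$ampMeans))
    widths <- pmax(0.02, stats::rnorm(5, p$widthMeans,
                                      p$betweenSDFrac * p$widthMeans))
    hr <- min(100, max(50, stats::rnorm(1, p$hrMean, p$hrBetweenSD)))
    hrSD <- max(0.5, stats::rnorm(1, p$hrSDMean, p$hrSDBetweenSD))
    new("SubjectParams", thetas = thetas, amps = amps, widths = widths,
        meanHR = hr, hrSD = hrSD, jitterSD = p$withinJitter,
        subjectId = sprintf("S%02d", index))
  })
}

#' Generate one labelled synthetic ECG recording
#'
#' Beats are concatenated with per-beat RR intervals drawn from
#' Normal(60 / (meanHR * hrScale), cv-matched sd) truncated to the
#' physiological range; within each beat the phase sweeps \[-pi, pi)
#' linearly and the subject's wave parameters (amplitudes and widths
#' jittered per beat) shape the waveform. Baseline wander, powerline
#' interference and white noise are then added, scaled by the activity
#' profile. Deterministic given the seed.
#'
#' @param subject a [SubjectParams-class].
#' @param activityProf one element of [activityProfiles()].
#' @param duration seconds (>= one beat).
#' @param fs sampling rate in Hz (>= 100).
#' @param noise a [noiseConfig()].
#' @param seed integer seed.
#' @return an [ECGRecording-class] of `round(duration * fs)` samples.
#' @examples
#' pop <- populationConfig()
#' sub <- sampleSubject(pop, 1)
#' rec <- generateRecording(sub, duration = 10, seed = 7)
#' @export
generateRecording <- function(subject,
                              activityProf = activityProfiles("resting")[[1]],
                              duration = 120, fs = 128,
                              noise = noiseConfig(), seed = 1L) {
  stopifnot(is(subject, "SubjectParams"),
            inherits(activityProf, "ActivityProfile"))
  validObject(subject)
  if (fs < 100) stop("fs must be at least 100 Hz")
  hr <- subject@meanHR * activityProf$hrScale
  if (hr < 30 || hr > 220)
    stop(sprintf(
      "non-physical configuration: activity-scaled heart rate %.1f bpm outside [30, 220]",
      hr))
  meanRR <- 60 / hr
  if (duration < meanRR) stop("duration must cover at least one beat")
  n <- as.integer(round(duration * fs))
  .withSeed(seed, {
    # RR intervals: preserve the subject's heart-rate cv under activity scaling
    rrSD <- meanRR * (subject@hrSD / subject@meanHR)
    nBeats <- ceiling(duration / meanRR * 1.3) + 5L
    rr <- stats::rnorm(nBeats, meanRR, rrSD)
    rr <- pmin(2, pmax(60 / 220, rr))
    while (sum(rr) < duration + meanRR) {
      extra <- pmin(2, pmax(60 / 220, stats::rnorm(10, meanRR, rrSD)))
      rr <- c(rr, extra)
    }
    nBeats <- length(rr)
    starts <- c(0, cumsum(rr))[seq_len(nBeats)]
    j <- subject@jitterSD
    ampJ <- matrix(1 + stats::rnorm(nBeats * 5, 0, j), nBeats, 5)
    widJ <- matrix(pmax(0.2, 1 + stats::rnorm(nBeats * 5, 0, j)), nBeats, 5)
    t <- (seq_len(n) - 1) / fs
    bi <- findInterval(t, starts)
    phase <- -pi + 2 * pi * (t - starts[bi]) / rr[bi]
    z <- numeric(n)
    for (k in 1:5) {
      a <- subject@amps[k] * ampJ[cbind(bi, k)]
      b <- subject@widths[k] * widJ[cbind(bi, k)]
      z <- z + a * exp(-(phase - subject@thetas[k])^2 / (2 * b^2))
    }
    wAmp <- noise$wanderAmp * activityProf$baselineWanderScale
    z <- z + wAmp * sin(2 * pi * noise$wanderFreq * t +
                          stats::runif(1, 0, 2 * pi))
    z <- z + noise$powerlineAmp * sin(2 * pi * noise$powerlineFreq * t +
                                        stats::runif(1, 0, 2 * pi))
    z <- z + stats::rnorm(n, 0, noise$whiteSD * activityProf$motionNoiseScale)
    ecgRecording(z, fs, subjectId = subject@subjectId,
                 activity = activityProf$name)
  })
}

#' Generate a full labelled cohort
#'
#' One recording per (subject, activity) pair; subjects and recordings get
#' independent substreams derived from the cohort seed by stable hashing of
#' their indices, so any single recording is reproducible in isolation.
#'
#' @param population a [populationConfig()].
#' @param activities character vector of activity names or a list from
#'   [activityProfiles()].
#' @param durationPerActivity seconds of signal per recording.
#' @param seed cohort seed; defaults to the population's.
#' @return list of [ECGRecording-class], ordered subject-major.
#' @examples
#' recs <- generateCohort(populationConfig(nSubjects = 2), "resting", 10)
#' length(recs)
#' @export
generateCohort <- function(population, activities = "resting",
                           durationPerActivity = 120,
                           seed = population$seed) {
  stopifnot(inherits(population, "PopulationConfig"))
  if (is.character(activities)) activities <- activityProfiles(activities)
  out <- vector("list", population$nSubjects * length(activities))
  idx <- 1L
  for (i in seq_len(population$nSubjects)) {
    subj <- sampleSubject(population, i, seed)
    for (jj in seq_along(activities)) {
      out[[idx]] <- generateRecording(
        subj, activities[[jj]], duration = durationPerActivity,
        fs = population$samplingRate, noise = population$noise,
        seed = .deriveSeed(seed, i, jj))
      idx <- idx + 1L
    }
  }
  out
}

#' Preprocess and encode a set of recordings into one GAFDataset
#'
#' Convenience composition used by the end-to-end experiments: each
#' recording is cleaned ([preprocessRecording()]) and its windows encoded
#' ([encodeSegments()]); the per-recording stacks are concatenated.
#'
#' @param recordings list of [ECGRecording-class].
#' @param config a [preprocessConfig()].
#' @param paaSize GAF image side length.
#' @param mode rescale mode.
#' @return a [GAFDataset-class] with subject labels per image.
#' @export
cohortToGAF <- function(recordings, config = preprocessConfig(),
                        paaSize = 64L, mode = c("symmetric", "unit")) {
  mode <- match.arg(mode)
  imgs <- list()
  for (rec in recordings) {
    segs <- preprocessRecording(rec, config)
    imgs <- c(imgs, lapply(segs, encodeSegment, paaSize = paaSize,
                           mode = mode))
  }
  gafDataset(imgs, meta = list(windowSeconds = config$windowSeconds,
                               paaSize = as.integer(paaSize),
                               rescaleMode = mode,
                               source = "synthetic cohort"))
}
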