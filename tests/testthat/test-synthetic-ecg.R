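test_that("subject sampling is deterministic per (seed, index) and varies across them", {
  pop <- tinyPopulation()
  s1a <- sampleSubject(pop, 1, seed = 1)
  s1b <- sampleSubject(pop, 1, seed = 1)
  expect_equal(s1a@amps, s1b@amps)
  expect_equal(s1a@thetas, s1b@thetas)
  s2 <- sampleSubject(pop, 2, seed = 1)
  sOther <- sampleSubject(pop, 1, seed = 2)
  expect_false(isTRUE(all.equal(s1a@amps, s2@amps)))
  expect_false(isTRUE(all.equal(s1a@amps, sOther@amps)))
  # invariants of the draw
  expect_true(all(diff(s1a@thetas) > 0))
  expect_true(all(s1a@widths > 0))
  expect_gte(s1a@meanHR, 50)
  expect_lte(s1a@meanHR, 100)
})

test_that("the identifiability guard rejects flat populations", {
  expect_error(populationConfig(betweenSDFrac = 0.02, withinJitter = 0.03),
               "identifiability")
})

test_that("between-subject R-amplitude spread dominates within-subject jitter", {
  pop <- tinyPopulation()
  aR <- vapply(1:50, function(i) sampleSubject(pop, i, seed = 42)@amps[3],
               numeric(1))
  meanAbsDiff <- mean(abs(outer(aR, aR, "-")[lower.tri(diag(50))]))
  withinSD <- pop$withinJitter * abs(pop$ampMeans[3])
  expect_gt(meanAbsDiff, 3 * withinSD)
})

test_that("recordings have the requested length, labels and determinism", {
  sub <- sampleSubject(tinyPopulation(), 1, seed = 7)
  act <- activityProfiles("walking")[[1]]
  r1 <- generateRecording(sub, act, duration = 10, fs = 128, seed = 3)
  r2 <- generateRecording(sub, act, duration = 10, fs = 128, seed = 3)
  expect_identical(ecgSamples(r1), ecgSamples(r2))
  expect_length(ecgSamples(r1), 1280)
  expect_equal(subjectId(r1), subjectId(sub))
  expect_equal(activity(r1), "walking")
})

test_that("a 10 s resting recording contains a plausible number of beats", {
  # beat count = duration / mean RR; configured resting HR range is
  # 50-100 bpm so 10 s holds 8..17 R peaks
  pop <- tinyPopulation()
  for (i in 1:5) {
    sub <- sampleSubject(pop, i, seed = 2)
    rec <- generateRecording(sub, duration = 10, fs = 128,
                             noise = noiseConfig(wanderAmp = 0, powerlineAmp = 0,
                                                 whiteSD = 0), seed = i)
    x <- ecgSamples(rec)
    thr <- max(x) * 0.6
    above <- x > thr
    peaks <- sum(diff(above) == 1)
    expect_gte(peaks, 8)
    expect_lte(peaks, 17)
  }
})

test_that("noiseless jitter-free recordings are periodic to machine precision", {
  pop <- tinyPopulation()
  sub <- sampleSubject(pop, 1, seed = 5)
  sub@meanHR <- 60          # RR = 1 s -> exactly 128 samples per beat
  sub@hrSD <- 0
  sub@jitterSD <- 0
  rec <- generateRecording(sub, duration = 10, fs = 128,
                           noise = noiseConfig(wanderAmp = 0,
                                               powerlineAmp = 0, whiteSD = 0),
                           seed = 9)
  x <- ecgSamples(rec)
  expect_lt(max(abs(x[1:128] - x[129:256])), 1e-9)
  expect_lt(max(abs(x[1:512] - x[513:1024])), 1e-9)
})

test_that("activity scaling halves the RR interval for running vs resting", {
  pop <- tinyPopulation()
  sub <- sampleSubject(pop, 1, seed = 4)
  sub@hrSD <- 0; sub@jitterSD <- 0
  quiet <- noiseConfig(wanderAmp = 0, powerlineAmp = 0, whiteSD = 0)
  rrOf <- function(act) {
    rec <- generateRecording(sub, activityProfiles(act)[[1]], duration = 20,
                             fs = 128, noise = quiet, seed = 8)
    x <- ecgSamples(rec)
    pk <- which(diff(x > max(x) * 0.6) == 1)
    mean(diff(pk)) / 128
  }
  expect_equal(rrOf("running") / rrOf("resting"), 0.5, tolerance = 0.01)
})

test_that("wander and powerline components appear at their configured frequencies", {
  pop <- tinyPopulation()
  sub <- sampleSubject(pop, 1, seed = 6)
  nz <- noiseConfig(wanderFreq = 0.3, wanderAmp = 1.5, powerlineFreq = 50,
                    powerlineAmp = 1.0, whiteSD = 0)
  rec <- generateRecording(sub, duration = 60, fs = 128, noise = nz, seed = 2)
  x <- ecgSamples(rec) - mean(ecgSamples(rec))
  spec <- Mod(stats::fft(x))[1:(length(x) / 2)]
  freqs <- (seq_along(spec) - 1) * 128 / length(x)
  lowPeak <- freqs[freqs < 1][which.max(spec[freqs < 1])]
  expect_lt(abs(lowPeak - 0.3), 0.05)
  hi <- freqs > 45
  hiPeak <- freqs[hi][which.max(spec[hi])]
  expect_lt(abs(hiPeak - 50), 0.5)
})

test_that("default cleaning removes >= 90% of wander and powerline power", {
  pop <- tinyPopulation()
  sub <- sampleSubject(pop, 1, seed = 3)
  rec <- generateRecording(sub, duration = 60, fs = 128,
                           noise = noiseConfig(), seed = 13)
  filtered <- bandpassFilter(removeDC(rec))
  bandPower <- function(r, lo, hi) {
    x <- ecgSamples(r) - mean(ecgSamples(r))
    spec <- Mod(stats::fft(x))^2
    freqs <- (seq_along(spec) - 1) * samplingRate(r) / length(x)
    sum(spec[freqs >= lo & freqs <= hi])
  }
  expect_lt(bandPower(filtered, 0.05, 0.55) / bandPower(rec, 0.05, 0.55), 0.1)
  expect_lt(bandPower(filtered, 49, 51) / bandPower(rec, 49, 51), 0.1)
})

test_that("cohorts have the right cardinality and reproduce from the seed", {
  pop <- populationConfig(nSubjects = 3, seed = 77)
  recs <- generateCohort(pop, c("resting", "math"), durationPerActivity = 5)
  expect_length(recs, 6)
  expect_equal(sort(unique(vapply(recs, subjectId, ""))),
               c("S01", "S02", "S03"))
  expect_setequal(unique(vapply(recs, activity, "")), c("resting", "math"))
  recs2 <- generateCohort(pop, c("resting", "math"), durationPerActivity = 5)
  expect_identical(lapply(recs, ecgSamples), lapply(recs2, ecgSamples))
})

test_that("non-physical activity scaling is rejected", {
  pop <- tinyPopulation()
  sub <- sampleSubject(pop, 1, seed = 1)
  sub@meanHR <- 115
  act <- activityProfiles("running")[[1]]  # x2.0 -> 230 bpm
  expect_error(generateRecording(sub, act, duration = 10), "non-physical")
  expect_error(activityProfiles("flying"), "unknown activity")
})
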