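# shared fixtures, all generated in code

# a short sinusoidal "recording" with known content
sineRecording <- function(freqHz, seconds = 10, fs = 128, amp = 1,
                          subject = "S01") {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  ecgRecording(amp * sin(2 * pi * freqHz * t), fs, subjectId = subject)
}

# small labelled GAF dataset built from random valid matrices
toyGAFDataset <- function(nPerClass = 5, classes = c("A", "B"), n = 8,
                          seed = 1) {
  set.seed(seed)
  count <- nPerClass * length(classes)
  imgs <- array(0, dim = c(n, n, count))
  for (i in seq_len(count)) {
    x <- runif(n, -1, 1)
    phi <- acos(x)
    imgs[, , i] <- cos(outer(phi, phi, "+"))
  }
  gafDataset(imgs, labels = rep(classes, each = nPerClass))
}

# the closed-form GASF oracle: x x' - sqrt(1-x^2) sqrt(1-x'^2)
gasfOracle <- function(x) {
  s <- sqrt(pmax(0, 1 - x^2))
  outer(x, x) - outer(s, s)
}

# tiny population for fast cohort tests
tinyPopulation <- function(n = 2, seed = 1) {
  populationConfig(nSubjects = n, seed = seed)
}

# small desk-scale model config that trains in seconds
tinyModelConfig <- function(numClasses, ...) {
  modelConfig("desk", numClasses = numClasses, inputSize = 16L,
              stemFilters = c(4L, 6L), coreFilters = 8L, hiddenUnits = 16L,
              batchSize = 8L, ...)
}
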