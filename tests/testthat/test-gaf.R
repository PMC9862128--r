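test_that("symmetric rescale maps extremes to -1/+1 and matches the closed form", {
  expect_equal(rescaleSeries(c(0, 1, 2))$values, c(-1, 0, 1))
  expect_equal(rescaleSeries(c(0, 2, 4, 6))$values, c(-1, -1/3, 1/3, 1))
  expect_equal(rescaleSeries(c(0, 2, 4, 6), "unit")$values, c(0, 1/3, 2/3, 1))
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(50)
    v <- rescaleSeries(x)$values
    expect_equal(min(v), -1)
    expect_equal(max(v), 1)
    # direct evaluation of the symmetric min-max map
    expect_equal(v, ((x - max(x)) + (x - min(x))) / (max(x) - min(x)))
  }
})

test_that("rescale rejects degenerate and non-finite input", {
  expect_error(rescaleSeries(c(5, 5, 5)), "degenerate")
  expect_error(rescaleSeries(c(1, NA, 2)), "finite")
  expect_error(rescaleSeries(numeric(0)), "non-empty")
})

test_that("polar transform maps endpoints correctly and clamps rounding spill", {
  p <- toPolar(c(1, 0, -1), nReg = 3)
  expect_equal(p$angles, c(0, pi / 2, pi))
  expect_equal(p$radii, c(1, 2, 3) / 3)
  # spill within 1e-12 is clamped, beyond is an error
  expect_equal(toPolar(1 + 1e-15)$angles, 0)
  expect_error(toPolar(1.001), "outside")
  expect_error(toPolar(0.5, nReg = -1), "positive")
})

test_that("PAA computes frame means, preserves constants and the identity case", {
  expect_equal(paa(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(paa(rep(2, 6), 4), rep(2, 4))
  x <- rnorm(37)
  expect_identical(paa(x, 37), x)
  expect_error(paa(1:4, 5), "exceeds")
  expect_error(paa(1:4, 0), "at least 1")
})

test_that("PAA preserves the global mean, also for fractional frames", {
  set.seed(7)
  for (nm in list(c(64, 8), c(640, 64), c(10, 3), c(17, 5))) {
    x <- rnorm(nm[1])
    expect_equal(mean(paa(x, nm[2])), mean(x), tolerance = 1e-12)
  }
})

test_that("gasf matches the algebraic oracle on many random series", {
  set.seed(123)
  worst <- 0
  for (i in 1:1000) {
    x <- runif(sample(4:24, 1), -1, 1)
    g <- gramMatrix(gasf(x))
    worst <- max(worst, max(abs(g - gasfOracle(x))))
  }
  expect_lt(worst, 1e-10)
})

test_that("gasf output is symmetric, bounded, with diagonal 2x^2 - 1", {
  expect_equal(gramMatrix(gasf(c(-1, 0, 1))),
               matrix(c(1, 0, -1, 0, -1, 0, -1, 0, 1), 3), tolerance = 1e-12)
  expect_equal(gramMatrix(gasf(1)), matrix(1, 1, 1))
  set.seed(99)
  for (i in 1:50) {
    x <- runif(16, -1, 1)
    g <- gramMatrix(gasf(x))
    expect_identical(g, t(g))
    expect_true(all(g >= -1 & g <= 1))
    expect_equal(diag(g), 2 * x^2 - 1, tolerance = 1e-10)
  }
})

test_that("rescale -> gasf -> recover round trip is exact in both modes", {
  expect_equal(recoverSeries(gasf(rescaleSeries(c(0, 2, 4, 6)))),
               c(-1, -1/3, 1/3, 1), tolerance = 1e-9)
  u <- rescaleSeries(c(0, 0.5, 1), "unit")
  expect_equal(recoverSeries(gasf(u)), c(0, 0.5, 1), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(sample(5:40, 1))
    for (mode in c("symmetric", "unit")) {
      r <- rescaleSeries(x, mode)
      expect_equal(recoverSeries(gasf(r)), r$values, tolerance = 1e-9)
    }
  }
})

test_that("recovery validates the diagonal", {
  img <- gasf(rescaleSeries(c(1, 2, 3)))
  bad <- img
  bad@gram[2, 2] <- 1.5
  expect_error(recoverSeries(bad), "diagonal")
})

test_that("the GASF is invariant under positive affine maps of the raw series", {
  set.seed(21)
  for (i in 1:25) {
    x <- rnorm(30)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    g1 <- gramMatrix(gasf(rescaleSeries(x)))
    g2 <- gramMatrix(gasf(rescaleSeries(a * x + b)))
    expect_equal(g1, g2, tolerance = 1e-12)
  }
})

test_that("encodeSegment composes PAA, rescale and gasf with provenance", {
  seg <- new("ECGSegment", samples = sin(seq(0, 20, length.out = 640)),
             samplingRate = 128, subjectId = "S07", activity = "walking",
             index = 3L)
  img <- encodeSegment(seg, paaSize = 128)
  expect_s4_class(img, "GAFImage")
  expect_equal(dim(gramMatrix(img)), c(128L, 128L))
  expect_equal(img@subjectId, "S07")
  expect_equal(img@segmentIndex, 3L)
  # m = n makes PAA the identity
  img2 <- encodeSegment(seg, paaSize = 640)
  expect_equal(gramMatrix(img2),
               gramMatrix(gasf(rescaleSeries(seg@samples))))
  # constant window propagates the degenerate-input error
  segc <- new("ECGSegment", samples = rep(1, 640), samplingRate = 128,
              subjectId = "S07", activity = "resting", index = 1L)
  expect_error(encodeSegment(segc), "degenerate")
})

test_that("image growth matches the n^2 expansion of the encoding", {
  seg <- new("ECGSegment", samples = rnorm(640), samplingRate = 128,
             subjectId = "x", activity = "unknown", index = 1L)
  for (m in c(16L, 64L)) {
    g <- gramMatrix(encodeSegment(seg, paaSize = m))
    expect_equal(length(g), as.numeric(m)^2)
  }
})
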