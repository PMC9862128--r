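test_that("model configuration validates architecture constraints", {
  cfg <- modelConfig("desk", numClasses = 10)
  expect_equal(cfg$coreConvLayers, 5L)
  expect_equal(cfg$coreKernel, 3L)
  full <- modelConfig("full")
  expect_equal(full$coreFilters, 512L)
  expect_equal(full$learningRate, 1e-5)
  expect_equal(full$dropoutCore, 0.25)
  expect_equal(full$dropoutHead, 0.10)
  expect_error(modelConfig("desk", numClasses = 1), "at least 2")
  expect_error(modelConfig("desk", inputSize = 8), "multiple of 8")
  expect_error(modelConfig("desk", learningRate = 0), "positive")
  expect_error(modelConfig("desk", dropoutCore = 1), "dropout")
})

test_that("built models expose a parameter count of the right order", {
  m <- buildModel(tinyModelConfig(3))
  expect_gt(numParameters(m), 1000)
  full <- buildModel(modelConfig("full", numClasses = 10))
  # the full profile is a multi-million parameter network
  expect_gt(numParameters(full), 1e6)
  expect_lt(numParameters(full), 1e8)
})

test_that("pretrained stem requires a weights file", {
  cfg <- modelConfig("desk", numClasses = 2, usePretrainedStem = TRUE)
  expect_error(buildModel(cfg), "stemWeightsPath")
})

test_that("forward pass yields probability rows summing to 1, deterministically", {
  cfg <- tinyModelConfig(4)
  m <- buildModel(cfg)
  set.seed(31)
  imgs <- array(runif(16 * 16 * 7, -1, 1), c(16, 16, 7))
  ds <- gafDataset(imgs, labels = rep("x", 7))
  p1 <- predictProbs(m, ds)
  expect_equal(dim(p1), c(7L, 4L))
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 7), tolerance = 1e-6)
  expect_identical(p1, predictProbs(m, ds))
  # single image keeps matrix shape
  p2 <- predictProbs(m, gafDataset(imgs[, , 1, drop = FALSE], labels = "x"))
  expect_equal(dim(p2), c(1L, 4L))
})

test_that("forward pass matches a brute-force convolution oracle", {
  refForward <- function(w, img, poolAt) {
    conv <- function(X, W, b) {
      H <- dim(X)[1]; C <- dim(X)[3]; F <- nrow(W)
      out <- array(0, c(H, H, F))
      Xp <- array(0, c(H + 2, H + 2, C))
      Xp[2:(H + 1), 2:(H + 1), ] <- X
      for (f in 1:F) {
        acc <- matrix(b[f], H, H)
        for (c in 1:C) for (dj in -1:1) for (di in -1:1) {
          r <- (c - 1) * 9 + (dj + 1) * 3 + (di + 1) + 1
          acc <- acc + W[f, r] * Xp[(2:(H + 1)) + di, (2:(H + 1)) + dj, c]
        }
        out[, , f] <- pmax(acc, 0)
      }
      out
    }
    pool <- function(X) {
      H <- dim(X)[1] / 2; F <- dim(X)[3]
      out <- array(0, c(H, H, F))
      for (f in 1:F) for (i in 1:H) for (j in 1:H)
        out[i, j, f] <- max(X[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), f])
      out
    }
    X <- array(img, c(dim(img), 1))
    for (l in seq_along(w$Wc)) {
      X <- conv(X, w$Wc[[l]], w$bc[[l]])
      if (l %in% poolAt) X <- pool(X)
    }
    g <- apply(X, 3, mean)
    h <- pmax(as.numeric(w$W1 %*% g + w$b1), 0)
    o <- as.numeric(w$W2 %*% h + w$b2)
    e <- exp(o - max(o))
    e / sum(e)
  }
  cfg <- tinyModelConfig(3, seed = 77)
  m <- buildModel(cfg)
  set.seed(78)
  img <- matrix(runif(256, -1, 1), 16, 16)
  got <- predictProbs(m, gafDataset(array(img, c(16, 16, 1)), labels = "q"))
  want <- refForward(m@weights, img, poolAt = c(2, 4, 9))
  # the network computes in single precision, the oracle in double
  expect_equal(as.numeric(got), want, tolerance = 1e-5)
})

test_that("training is seeded, improves the loss, and restores the best epoch", {
  ds <- toyGAFDataset(nPerClass = 12, classes = c("A", "B"), n = 16, seed = 5)
  # make the classes separable: shift class B images
  imgs <- gafImages(ds)
  imgs[, , gafLabels(ds) == "B"] <-
    pmax(-1, imgs[, , gafLabels(ds) == "B"] - 0.6)
  ds <- gafDataset(imgs, labels = gafLabels(ds))
  sp <- splitDataset(ds, c(0.7, 0.3), seed = 2)
  cfg <- tinyModelConfig(2, maxEpochs = 60L, patience = 60L, seed = 6)
  m1 <- trainModel(buildModel(cfg), sp$train, sp$test, seed = 6)
  m2 <- trainModel(buildModel(cfg), sp$train, sp$test, seed = 6)
  expect_identical(m1@weights, m2@weights)
  h <- trainingHistory(m1)
  expect_lt(tail(h@epochs$trainLoss, 1), h@epochs$trainLoss[1])
  expect_lte(h@bestEpoch, h@stoppedEpoch)
  expect_gte(tail(h@epochs$trainAcc, 1), 0.9)
})

test_that("patience 0 stops at the first non-improving epoch", {
  ds <- toyGAFDataset(nPerClass = 6, classes = c("A", "B"), n = 16, seed = 8)
  sp <- splitDataset(ds, c(0.5, 0.5), seed = 1)
  cfg <- tinyModelConfig(2, maxEpochs = 50L, patience = 0L, seed = 3)
  m <- trainModel(buildModel(cfg), sp$train, sp$test, seed = 3)
  h <- trainingHistory(m)
  vl <- h@epochs$valLoss
  firstStall <- which(diff(vl) >= 0)[1] + 1
  expect_equal(h@stoppedEpoch, ifelse(is.na(firstStall), 50, firstStall))
})

test_that("a class present only in validation is rejected", {
  tr <- toyGAFDataset(nPerClass = 4, classes = c("A", "B"), n = 16)
  va <- toyGAFDataset(nPerClass = 2, classes = c("C"), n = 16)
  cfg <- tinyModelConfig(2)
  expect_error(trainModel(buildModel(cfg), tr, va), "absent from training")
})

test_that("the desk-scale network can memorise a small 2-class set", {
  # capacity check: 16 images, 2 classes, within 100 epochs
  set.seed(44)
  imgs <- array(runif(16 * 16 * 16, -1, 1), c(16, 16, 16))
  lab <- rep(c("A", "B"), each = 8)
  imgs[, , lab == "B"] <- pmin(1, imgs[, , lab == "B"] + 0.3)
  ds <- gafDataset(imgs, labels = lab)
  cfg <- tinyModelConfig(2, maxEpochs = 100L, patience = 100L, seed = 9)
  m <- trainModel(buildModel(cfg), ds, ds, seed = 9)
  expect_equal(max(trainingHistory(m)@epochs$trainAcc), 1)
})

test_that("mismatched image size is rejected at predict and train time", {
  m <- buildModel(tinyModelConfig(2))
  ds <- toyGAFDataset(nPerClass = 3, classes = c("A", "B"), n = 8)
  expect_error(predictProbs(m, ds), "expects")
  expect_error(predictProbs(m, gafDataset(list())), "empty")
})
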