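test_that("stratified splits preserve per-class counts and are deterministic", {
  ds <- toyGAFDataset(nPerClass = 100, classes = paste0("u", 1:10), n = 4)
  sp <- splitDataset(ds, c(0.8, 0.1, 0.1), seed = 3)
  for (part in sp) {
    counts <- table(gafLabels(part))
    expect_equal(length(counts), 10)
  }
  expect_equal(unname(table(gafLabels(sp$train))), rep(80L, 10),
               ignore_attr = TRUE)
  expect_equal(unname(table(gafLabels(sp$val))), rep(10L, 10),
               ignore_attr = TRUE)
  expect_equal(unname(table(gafLabels(sp$test))), rep(10L, 10),
               ignore_attr = TRUE)
  sp2 <- splitDataset(ds, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(gafImages(sp$train), gafImages(sp2$train))
  expect_identical(gafLabels(sp$test), gafLabels(sp2$test))
})

test_that("splits partition the dataset with no image in two parts", {
  ds <- toyGAFDataset(nPerClass = 13, classes = c("a", "b", "c"), n = 5)
  sp <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = 9)
  expect_equal(sum(vapply(sp, nImages, 1L)), nImages(ds))
  # fingerprint each image to verify disjointness
  fp <- function(part) apply(gafImages(part), 3, function(m) sum(m * seq_along(m)))
  all_fp <- unlist(lapply(sp, fp))
  expect_equal(anyDuplicated(all_fp), 0)
})

test_that("splitting rejects classes too small to stratify", {
  ds <- toyGAFDataset(nPerClass = 2, classes = c("a", "b"), n = 4)
  expect_error(splitDataset(ds, c(0.8, 0.1, 0.1), seed = 1), "fewer images")
})

test_that("confusion matrix counts probes with exact row sums", {
  cm <- confusionMatrix(rep(c("a", "b", "c"), each = 5),
                        rep(c("a", "b", "c"), each = 5))
  expect_equal(diag(cm), c(a = 5L, b = 5L, c = 5L))
  expect_equal(sum(cm), 15)
  cm2 <- confusionMatrix(rep("A", 5), rep("B", 5), classes = c("A", "B"))
  expect_equal(cm2, matrix(c(0L, 0L, 5L, 0L), 2,
                           dimnames = list(truth = c("A", "B"),
                                           predicted = c("A", "B"))))
  set.seed(4)
  truth <- sample(letters[1:4], 200, replace = TRUE)
  pred <- sample(letters[1:4], 200, replace = TRUE)
  cm3 <- confusionMatrix(truth, pred, letters[1:4])
  expect_equal(sum(cm3), 200)
  expect_equal(rowSums(cm3), table(factor(truth, letters[1:4])),
               ignore_attr = TRUE)
  expect_error(confusionMatrix("a", "z", classes = "a"), "outside")
})

test_that("metrics reproduce the balanced closed form FRR/(C-1) = FAR", {
  # 10 classes x 300 probes, 27 misclassifications per class spread evenly
  C <- 10
  cm <- matrix(3L, C, C)
  diag(cm) <- 273L
  rep <- identificationMetrics(cm)
  expect_equal(rep@accuracy, 0.91)
  expect_equal(rep@FRR, 0.09)
  expect_equal(rep@FAR, 0.01)
  expect_equal(rep@K, 9)
})

test_that("K is C-1 for any balanced confusion matrix (brute-force oracle)", {
  set.seed(8)
  for (i in 1:100) {
    C <- sample(3:12, 1)
    n <- 50
    truth <- rep(seq_len(C), each = n)
    pred <- truth
    nflip <- sample(1:(C * n %/% 3), 1)
    at <- sample(length(pred), nflip)
    pred[at] <- vapply(truth[at], function(t) sample(setdiff(seq_len(C), t), 1), 1L)
    cm <- confusionMatrix(truth, pred, seq_len(C))
    rep <- identificationMetrics(cm)
    # naive per-probe counting oracle
    frrOracle <- mean(pred != truth)
    farOracle <- mean(vapply(seq_len(C), function(i)
      sum(pred == i & truth != i) / sum(truth != i), numeric(1)))
    expect_equal(rep@FRR, frrOracle)
    expect_equal(rep@FAR, farOracle)
    if (frrOracle > 0) expect_equal(rep@K, C - 1)
  }
})

test_that("metrics agree with a per-probe counting oracle on unbalanced data", {
  set.seed(15)
  for (i in 1:100) {
    C <- sample(2:6, 1)
    classes <- paste0("u", seq_len(C))
    truth <- sample(classes, 120, replace = TRUE, prob = runif(C, 0.5, 2))
    pred <- ifelse(runif(120) < 0.7, truth, sample(classes, 120, replace = TRUE))
    cm <- confusionMatrix(truth, pred, classes)
    rep <- identificationMetrics(cm)
    expect_equal(rep@accuracy, mean(pred == truth))
    expect_equal(rep@FRR, mean(pred != truth))
    farOracle <- mean(vapply(classes, function(cl)
      sum(pred == cl & truth != cl) / sum(truth != cl), numeric(1)))
    expect_equal(rep@FAR, farOracle)
  }
})

test_that("perfect identification gives zero rates and undefined K", {
  rep <- identificationMetrics(diag(5L, 3))
  expect_equal(rep@accuracy, 1)
  expect_equal(rep@FRR, 0)
  expect_equal(rep@FAR, 0)
  expect_true(is.na(rep@K))
  expect_error(identificationMetrics(matrix(0L, 2, 2)), "empty")
  expect_error(identificationMetrics(matrix(1L, 2, 3)), "square")
})

test_that("the printed error rates of a 10-user experiment give K = 9", {
  expect_equal(round(kRatio(far = 0.01022, frr = 0.09254)), 9)
  expect_true(is.na(kRatio(0, 0.5)))
  expect_error(kRatio(-0.1, 0.5), "non-negative")
})

test_that("threshold rejection is monotone: FRR rises, FAR falls", {
  set.seed(23)
  C <- 5
  classes <- paste0("u", seq_len(C))
  truth <- sample(classes, 200, replace = TRUE)
  raw <- matrix(rexp(200 * C), 200, C,
                dimnames = list(NULL, classes))
  raw[cbind(seq_len(200), match(truth, classes))] <-
    raw[cbind(seq_len(200), match(truth, classes))] + runif(200, 0, 4)
  probs <- raw / rowSums(raw)
  taus <- seq(0, 1, by = 0.1)
  reports <- lapply(taus, function(tau)
    identificationMetrics(threshold = tau, probabilities = probs,
                          truth = truth, classes = classes))
  frr <- vapply(reports, function(r) r@FRR, numeric(1))
  far <- vapply(reports, function(r) r@FAR, numeric(1))
  expect_true(all(diff(frr) >= 0))
  expect_true(all(diff(far) <= 0))
  # tau = 1 rejects everything
  last <- identificationMetrics(threshold = 1 + 1e-9, probabilities = probs,
                                truth = truth, classes = classes)
  expect_equal(last@FRR, 1)
  expect_equal(last@FAR, 0)
  # accuracy + FRR = 1 without a threshold
  none <- identificationMetrics(probabilities = probs, truth = truth,
                                classes = classes)
  expect_equal(none@accuracy + none@FRR, 1)
})
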