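#' Stratified train / validation / test split
#'
#' Partitions a [GAFDataset-class] into disjoint subsets. In stratified
#' mode (default) each class is split separately so class proportions are
#' preserved within one image; counts per class are `round(f * n)` for the
#' first splits and the remainder for the last. Deterministic given the
#' seed.
#'
#' @param dataset a [GAFDataset-class].
#' @param fractions positive fractions summing to 1; the classical protocol
#'   is 0.8 / 0.1 / 0.1 (train/val/test). Two-way splits (e.g. 0.8 / 0.2)
#'   are allowed.
#' @param stratified split within each class (default) or uniformly.
#' @param seed split seed.
#' @return named list of [GAFDataset-class] objects (`train`, `val`,
#'   `test`; or `train`, `test` for two-way splits).
#' @export
splitDataset <- function(dataset, fractions = c(0.8, 0.1, 0.1),
                         stratified = TRUE, seed = 1L) {
  stopifnot(is(dataset, "GAFDataset"))
  validObject(dataset)
  if (any(fractions <= 0)) stop("fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  k <- length(fractions)
  if (k < 2L) stop("need at least two splits")
  n <- nImages(dataset)
  labs <- gafLabels(dataset)
  if (stratified) {
    short <- names(which(table(labs) < k))
    if (length(short))
      stop("classes with fewer images than splits: ",
           paste(short, collapse = ", "))
  }
  assign_group <- function(m) {
    # largest-remainder apportionment, then guarantee every split >= 1 by
    # borrowing from the largest
    sizes <- floor(fractions * m)
    rem <- fractions * m - sizes
    short <- m - sum(sizes)
    if (short > 0) {
      ord <- order(rem, decreasing = TRUE)
      sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1L
    }
    while (any(sizes == 0)) {
      sizes[which.max(sizes == 0)] <- 1L
      sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    }
    rep.int(seq_len(k), sizes)
  }
  groups <- integer(n)
  .withSeed(seed, {
    if (stratified) {
      for (cl in unique(labs)) {
        idx <- which(labs == cl)
        groups[idx] <- sample(assign_group(length(idx)))
      }
    } else {
      groups <- sample(assign_group(n))
    }
  })
  parts <- lapply(seq_len(k), function(g) {
    sel <- which(groups == g)
    new("GAFDataset",
        images = dataset@images[, , sel, drop = FALSE],
        labels = dataset@labels[sel],
        activities = if (length(dataset@activities))
          dataset@activities[sel] else character(0),
        meta = dataset@meta)
  })
  names(parts) <- if (k == 3L) c("train", "val", "test")
                  else if (k == 2L) c("train", "test")
                  else paste0("split", seq_len(k))
  parts
}

#' Confusion matrix of an identification experiment
#'
#' @param truth true class labels.
#' @param predicted predicted class labels (same length).
#' @param classes class order for rows/columns; defaults to the sorted
#'   union of labels.
#' @return C x C integer matrix; entry \[i, j\] counts probes of class i
#'   predicted as class j.
#' @export
confusionMatrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% classes) || !all(predicted %in% classes))
    stop("labels outside the supplied class order")
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  m <- table(tf, pf)
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(truth = classes, predicted = classes))
  out
}

#' Closed-set identification metrics: accuracy, FRR, FAR, K
#'
#' In the closed-set (one-to-many) setting every probe belongs to an
#' enrolled user. A genuine probe of user i that is not labelled i is a
#' false rejection, so FRR is the misclassification rate; FAR is the
#' macro-average over identities i of the rate at which probes of *other*
#' users are accepted as i. For balanced classes these definitions tie FAR
#' to FRR / (C - 1) exactly, hence K = FRR / FAR = C - 1. K is reported as
#' `NA` when FAR is zero.
#'
#' With a rejection threshold `threshold` and a probability matrix, probes
#' whose top probability falls below the threshold are rejected: genuine
#' rejections count toward FRR and rejected probes are excluded from
#' false-accept counts.
#'
#' @param confusion a square count matrix (rows = truth), as produced by
#'   [confusionMatrix()]. Ignored when `probabilities` is given.
#' @param threshold optional probability threshold in \[0, 1\].
#' @param probabilities optional N x C probability matrix (columns named or
#'   ordered as `classes`).
#' @param truth true labels, required with `probabilities`.
#' @param classes class order.
#' @return an [EvalReport-class].
#' @examples
#' cm <- diag(5L, 3)  # perfect identification
#' identificationMetrics(cm)
#' @export
identificationMetrics <- function(confusion = NULL, threshold = NULL,
                                  probabilities = NULL, truth = NULL,
                                  classes = NULL) {
  nRejected <- 0L
  if (!is.null(probabilities)) {
    if (is.null(truth)) stop("truth labels are required with probabilities")
    if (is.null(classes))
      classes <- colnames(probabilities) %||% sort(unique(truth))
    if (nrow(probabilities) != length(truth))
      stop("probabilities and truth sizes differ")
    pred <- classes[apply(probabilities, 1, which.max)]
    accepted <- rep(TRUE, length(truth))
    if (!is.null(threshold))
      accepted <- apply(probabilities, 1, max) >= threshold
    nRejected <- sum(!accepted)
    confusion <- confusionMatrix(truth[accepted], pred[accepted], classes)
  } else {
    if (is.null(confusion)) stop("supply a confusion matrix or probabilities")
    if (!is.null(threshold))
      stop("threshold mode needs the probability matrix, not just counts")
    if (nrow(confusion) != ncol(confusion))
      stop("confusion matrix must be square")
    classes <- classes %||% rownames(confusion) %||%
      paste0("C", seq_len(nrow(confusion)))
  }
  C <- nrow(confusion)
  totalProbes <- sum(confusion) + nRejected
  if (totalProbes == 0) stop("empty experiment: no probes")
  correct <- sum(diag(confusion))
  accuracy <- correct / totalProbes
  frr <- 1 - accuracy
  # per-identity false accepts: probes of other classes labelled i, over
  # all probes not of class i (rejected probes excluded from accepts)
  rowTot <- rowSums(confusion)
  genuineTot <- rowTot
  if (nRejected > 0L && !is.null(truth)) {
    genuineTot <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  }
  farPer <- vapply(seq_len(C), function(i) {
    impostors <- totalProbes - genuineTot[i]
    if (impostors == 0) return(0)
    (sum(confusion[, i]) - confusion[i, i]) / impostors
  }, numeric(1))
  far <- mean(farPer)
  k <- if (far > 0) frr / far else NA_real_
  perClass <- ifelse(genuineTot > 0, diag(confusion) / genuineTot, NA_real_)
  new("EvalReport", confusion = confusion, accuracy = accuracy,
      perClassAccuracy = as.numeric(perClass), FRR = frr, FAR = far,
      K = k, threshold = threshold %||% NA_real_,
      nRejected = as.integer(nRejected))
}

#' Ratio of false rejections to false acceptances
#'
#' The error-balance parameter K defined by K x FAR = FRR; K > 1 means a
#' false acceptance is K times rarer than a false rejection.
#'
#' @param far false acceptance rate (> 0).
#' @param frr false rejection rate.
#' @return K = FRR / FAR.
#' @examples
#' kRatio(far = 0.01022, frr = 0.09254)  # ~9
#' @export
kRatio <- function(far, frr) {
  if (far < 0 || frr < 0) stop("rates must be non-negative")
  if (far == 0) return(NA_real_)
  frr / far
}

#' Evaluate a trained model on a test set
#'
#' Composes [predictProbs()], optional threshold rejection,
#' [confusionMatrix()] and [identificationMetrics()].
#'
#' @param model a trained [GAFNet-class].
#' @param test a [GAFDataset-class] whose classes are enrolled in the
#'   model.
#' @param threshold optional rejection threshold on the top probability.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, test, threshold = NULL) {
  stopifnot(is(model, "GAFNet"), is(test, "GAFDataset"))
  if (nImages(test) == 0L) stop("empty test set")
  extra <- setdiff(unique(gafLabels(test)), model@classes)
  if (length(extra))
    stop("test classes not enrolled in the model: ",
         paste(extra, collapse = ", "))
  probs <- predictProbs(model, test)
  identificationMetrics(threshold = threshold, probabilities = probs,
                        truth = gafLabels(test), classes = model@classes)
}
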