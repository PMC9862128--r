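#' Rescale a series for angular encoding
#'
#' Symmetric mode maps the series onto \[-1, 1\] via
#' \deqn{\tilde x_i = \frac{(x_i - \max X) + (x_i - \min X)}{\max X - \min X}}
#' (the series minimum maps to -1 and the maximum to +1); unit mode is the
#' ordinary min-max map onto \[0, 1\]. The original extrema are retained so
#' the map can be undone. Both maps are invariant under positive affine
#' transformations of the input, which is why no amplitude calibration of
#' the ECG is needed upstream.
#'
#' @param series numeric vector, length >= 1, non-constant.
#' @param mode `"symmetric"` (default) or `"unit"`.
#' @return a list of class `"RescaledSeries"` with elements `values`,
#'   `mode`, `originalMin`, `originalMax`.
#' @examples
#' rescaleSeries(c(0, 2, 4, 6))$values  # -1 -1/3 1/3 1
#' @export
rescaleSeries <- function(series, mode = c("symmetric", "unit")) {
  mode <- match.arg(mode)
  if (length(series) < 1L) stop("series must be non-empty")
  if (anyNA(series) || any(!is.finite(series)))
    stop("series must be finite")
  lo <- min(series)
  hi <- max(series)
  if (hi == lo)
    stop("degenerate input: constant series has no angular spread to encode")
  values <- if (mode == "symmetric") {
    ((series - hi) + (series - lo)) / (hi - lo)
  } else {
    (series - lo) / (hi - lo)
  }
  structure(list(values = values, mode = mode,
                 originalMin = lo, originalMax = hi),
            class = "RescaledSeries")
}

.clampUnitBall <- function(x, tol = 1e-12) {
  bad <- abs(x) > 1 + tol
  if (any(bad))
    stop(sprintf("rescaled value outside [-1, 1] beyond tolerance (max |x| = %.3g)",
                 max(abs(x))))
  pmin(1, pmax(-1, x))
}

#' Polar representation of a rescaled series
#'
#' Angles \eqn{\phi_i = \arccos(\tilde x_i) \in [0, \pi]}; radii
#' \eqn{r_i = t_i / N} with \eqn{t_i} the 1-based time index and N a
#' regulation constant for the polar plot (default: the series length, so
#' radii span (0, 1\]). The radii carry the temporal ordering but do not
#' enter the Gramian matrix. Values beyond \[-1, 1\] by at most 1e-12
#' (floating-point spill) are clamped; larger excursions are errors.
#'
#' @param rescaled a [rescaleSeries()] result (or a bare numeric vector
#'   already inside \[-1, 1\]).
#' @param nReg regulation parameter N (> 0).
#' @return list of class `"PolarSeries"` with `angles` (radians), `radii`
#'   and `nReg`.
#' @export
toPolar <- function(rescaled, nReg = NULL) {
  x <- if (inherits(rescaled, "RescaledSeries")) rescaled$values else rescaled
  n <- length(x)
  if (is.null(nReg)) nReg <- n
  if (nReg <= 0) stop("regulation parameter nReg must be positive")
  x <- .clampUnitBall(x)
  structure(list(angles = acos(x), radii = seq_len(n) / nReg, nReg = nReg),
            class = "PolarSeries")
}

#' Piecewise aggregate approximation (PAA)
#'
#' Reduces a length-n series to length m by frame means. Frames partition
#' the time axis into m equal-width intervals; when m does not divide n the
#' boundary samples contribute fractionally to both adjacent frames, so the
#' global mean is preserved for every (n, m). `m == n` is the identity.
#'
#' @param series numeric vector of length n.
#' @param targetSize m, with 1 <= m <= n.
#' @return numeric vector of length m.
#' @examples
#' paa(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
paa <- function(series, targetSize) {
  n <- length(series)
  m <- as.integer(targetSize)
  if (m < 1L) stop("targetSize must be at least 1")
  if (m > n) stop(sprintf("targetSize (%d) exceeds series length (%d)", m, n))
  if (m == n) return(series)
  frame <- n / m
  out <- numeric(m)
  for (j in seq_len(m)) {
    a <- (j - 1) * frame  # frame covers [a, b) on the continuous index axis
    b <- j * frame
    i0 <- floor(a) + 1
    i1 <- ceiling(b)
    idx <- i0:min(i1, n)
    w <- pmin(idx, b) - pmax(idx - 1, a)
    out[j] <- sum(series[idx] * w) / frame
  }
  out
}

#' Gramian Angular Summation Field of a rescaled series
#'
#' Builds the n x n matrix \eqn{G_{ij} = \cos(\phi_i + \phi_j)} from the
#' polar angles of the rescaled series — algebraically
#' \eqn{\tilde x_i \tilde x_j - \sqrt{1-\tilde x_i^2}\sqrt{1-\tilde x_j^2}}.
#' G is symmetric with entries in \[-1, 1\] and diagonal
#' \eqn{G_{ii} = 2\tilde x_i^2 - 1}.
#'
#' @param rescaled a [rescaleSeries()] result (or numeric vector in
#'   \[-1, 1\]).
#' @param subjectId,activityLabel,segmentIndex optional provenance.
#' @return a [GAFImage-class].
#' @examples
#' gramMatrix(gasf(c(-1, 0, 1)))
#' @export
gasf <- function(rescaled, subjectId = "", activityLabel = "unknown",
                 segmentIndex = NA_integer_) {
  mode <- if (inherits(rescaled, "RescaledSeries")) rescaled$mode else "symmetric"
  x <- if (inherits(rescaled, "RescaledSeries")) rescaled$values else rescaled
  phi <- toPolar(rescaled)$angles
  g <- cos(outer(phi, phi, "+"))
  ref <- which(abs(x) >= max(abs(x)) - 1e-9)[1]
  new("GAFImage", gram = g, mode = mode,
      refSign = if (x[ref] >= 0) 1 else -1,
      subjectId = subjectId, activity = activityLabel,
      segmentIndex = as.integer(segmentIndex))
}

#' Encode one ECG window as a GAF image
#'
#' Composition PAA (on the raw window) -> rescale -> GASF; the output is a
#' `paaSize` x `paaSize` matrix carrying the window's provenance labels.
#'
#' @param segment an [ECGSegment-class] (or [ECGRecording-class]).
#' @param paaSize image side length m (<= window length); default 64.
#' @param mode rescale mode, `"symmetric"` or `"unit"`.
#' @return a [GAFImage-class].
#' @export
encodeSegment <- function(segment, paaSize = 64L,
                          mode = c("symmetric", "unit")) {
  mode <- match.arg(mode)
  stopifnot(is(segment, "ECGSegment") || is(segment, "ECGRecording"))
  x <- paa(segment@samples, paaSize)
  idx <- if (is(segment, "ECGSegment")) segment@index else NA_integer_
  gasf(rescaleSeries(x, mode), subjectId = segment@subjectId,
       activityLabel = segment@activity, segmentIndex = idx)
}

#' Encode a list of windows into a GAFDataset
#'
#' @param segments list of [ECGSegment-class] windows.
#' @param paaSize image side length.
#' @param mode rescale mode.
#' @param windowSeconds optional metadata: window length used upstream.
#' @param source optional metadata: free-form provenance string.
#' @return a [GAFDataset-class].
#' @export
encodeSegments <- function(segments, paaSize = 64L,
                           mode = c("symmetric", "unit"),
                           windowSeconds = NA_real_, source = "") {
  mode <- match.arg(mode)
  imgs <- lapply(segments, encodeSegment, paaSize = paaSize, mode = mode)
  gafDataset(imgs, meta = list(windowSeconds = windowSeconds,
                               paaSize = as.integer(paaSize),
                               rescaleMode = mode, source = source))
}

#' Recover the rescaled series from a GAF image
#'
#' The main diagonal gives \eqn{|\tilde x_i| = \sqrt{(G_{ii}+1)/2}}. In unit
#' mode the values are non-negative so this is the exact series — the
#' restoration-from-the-diagonal property holds unconditionally there. In
#' symmetric mode the diagonal fixes values only up to sign, and the GASF
#' matrix itself is invariant under global negation of the series, so signs
#' are resolved from the off-diagonal row of a reference index of known
#' sign: the temporally first largest-magnitude element, for which
#' \eqn{G_{rj} = \tilde x_r \tilde x_j} exactly, whose sign [gasf()] stores
#' as encoding metadata (`refSign`). Without that bit (`refSign` NA) the
#' reference is assumed positive and recovery is exact up to a possible
#' global sign flip.
#'
#' @param image a [GAFImage-class].
#' @param mode rescale mode used at encoding; defaults to the image's own.
#' @return numeric vector of recovered rescaled values.
#' @export
recoverSeries <- function(image, mode = NULL) {
  stopifnot(is(image, "GAFImage"))
  if (is.null(mode)) mode <- image@mode
  mode <- match.arg(mode, c("symmetric", "unit"))
  d <- diag(image@gram)
  if (any(abs(d) > 1 + 1e-9))
    stop("diagonal entry outside [-1, 1] beyond tolerance")
  absx <- sqrt(pmax(0, (pmin(1, d) + 1) / 2))
  if (mode == "unit") return(absx)
  r <- which(absx >= max(absx) - 1e-9)[1]
  s <- sign(image@gram[r, ])
  s[s == 0] <- 1
  ref <- if (is.na(image@refSign)) 1 else image@refSign
  ref * s * absx
}
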