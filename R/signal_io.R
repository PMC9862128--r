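#' Read a single-lead ECG recording
#'
#' Supported formats: `"csv"` — one sample per row in a column named
#' `amplitude`, with the sampling rate (and optionally subject / activity /
#' lead) given as `# key=value` header comments; `"rds"` — a serialized
#' [ECGRecording-class].
#'
#' @param path file path.
#' @param format `"csv"` or `"rds"`; default guesses from the extension.
#' @param samplingRate overrides / supplies the rate when the CSV lacks an
#'   `# fs=` comment.
#' @return an [ECGRecording-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeRecording(ecgRecording(rnorm(64), 128, "S01"), f)
#' rec <- readRecording(f)
#' @export
readRecording <- function(path, format = c("auto", "csv", "rds"),
                          samplingRate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "csv"
  }
  if (format == "rds") {
    rec <- readRDS(path)
    if (!is(rec, "ECGRecording"))
      stop("rds file does not contain an ECGRecording: ", path)
    validObject(rec)
    return(rec)
  }
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!"amplitude" %in% names(df))
    stop("CSV recording must have an 'amplitude' column: ", path)
  fs <- samplingRate
  if (is.null(fs) && !is.null(meta$fs)) fs <- suppressWarnings(as.numeric(meta$fs))
  if (is.null(fs) || is.na(fs))
    stop("sampling rate missing: supply '# fs=<Hz>' header or samplingRate=")
  if (fs <= 0) stop("sampling rate must be positive, got fs=", fs)
  x <- suppressWarnings(as.numeric(df$amplitude))
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite amplitude values in ", path)
  ecgRecording(x, fs,
               subjectId = meta$subject %||% "unknown",
               activity = meta$activity %||% "unknown",
               lead = meta$lead %||% "II-modified")
}

#' Write a recording as a commented CSV
#'
#' Inverse of [readRecording()]: emits `# key=value` header comments
#' (fs, subject, activity, lead) followed by an `amplitude` column.
#'
#' @param recording an [ECGRecording-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "ECGRecording"))
  validObject(recording)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", recording@samplingRate),
    sprintf("# subject=%s", recording@subjectId),
    sprintf("# activity=%s", recording@activity),
    sprintf("# lead=%s", recording@lead),
    "amplitude"), con)
  writeLines(sprintf("%.17g", recording@samples), con)
  invisible(path)
}

#' Write / read a GAF dataset container
#'
#' The native container is a compressed serialized list with keys `images`
#' (n x n x count array), `labels`, `activities` and `meta`; the write ->
#' read round trip is bit-exact for every matrix entry.
#'
#' @param dataset a [GAFDataset-class].
#' @param path destination (conventionally `.gaf.rds`).
#' @return `writeGAFDataset` returns `path` invisibly; `readGAFDataset`
#'   returns the [GAFDataset-class].
#' @export
writeGAFDataset <- function(dataset, path) {
  stopifnot(is(dataset, "GAFDataset"))
  validObject(dataset)
  saveRDS(list(images = dataset@images, labels = dataset@labels,
               activities = dataset@activities, meta = dataset@meta),
          path)
  invisible(path)
}

#' @rdname writeGAFDataset
#' @export
readGAFDataset <- function(path) {
  if (!file.exists(path)) stop("GAF dataset file does not exist: ", path)
  payload <- readRDS(path)
  need <- c("images", "labels")
  if (!is.list(payload) || !all(need %in% names(payload)))
    stop("not a GAF dataset container (missing images/labels): ", path)
  gafDataset(payload$images, labels = payload$labels,
             activities = payload$activities %||% NULL,
             meta = payload$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
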