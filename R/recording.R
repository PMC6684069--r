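#' Multichannel burst recordings
#'
#' A recording is a tibble with a `time` column (seconds, uniformly sampled)
#' and one column per channel. Channel names encode thoracic segment and body
#' side as `<segment>_<side>`, e.g. `meso_L`. The sampling rate, processing
#' stage (`"raw"` or `"preprocessed"`) and free-form provenance metadata ride
#' along as attributes; [rec_rate()] falls back to the time column if a dplyr
#' verb has stripped them.
#'
#' @param data Data frame with a numeric `time` column and numeric channel
#'   columns.
#' @param rate Sampling rate in Hz. Inferred from `time` when `NULL`.
#' @param stage `"raw"` or `"preprocessed"`.
#' @param meta Named list of provenance (seed, ground truth, ...).
#' @return A `cpg_recording` tibble.
#' @examples
#' rec <- as_recording(tibble::tibble(
#'   time = seq(0, 1, by = 0.01), meso_L = sin(seq(0, 1, by = 0.01))
#' ))
#' rec_rate(rec)
#' @export
as_recording <- function(data, rate = NULL, stage = "raw", meta = list()) {
  data <- tibble::as_tibble(data)
  if (!"time" %in% names(data)) {
    abort("recording must have a `time` column")
  }
  chans <- setdiff(names(data), "time")
  if (length(chans) == 0) abort("recording has no channel columns")
  lens <- vapply(data, length, integer(1))
  if (length(unique(lens)) != 1) abort("all channels must have equal length")
  dt <- diff(data$time)
  if (length(dt) > 0 && (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt))) {
    abort("recording requires uniform sampling: time steps are non-uniform or non-monotone")
  }
  if (is.null(rate)) rate <- 1 / stats::median(dt)
  stage <- match.arg(stage, c("raw", "preprocessed"))
  structure(data,
    class = c("cpg_recording", class(tibble::tibble())),
    rate = rate, stage = stage, meta = meta
  )
}

#' @rdname as_recording
#' @param rec A recording.
#' @export
rec_rate <- function(rec) {
  r <- attr(rec, "rate")
  if (is.null(r)) r <- 1 / stats::median(diff(rec$time))
  r
}

#' @rdname as_recording
#' @export
rec_stage <- function(rec) attr(rec, "stage") %||% "raw"

#' @rdname as_recording
#' @export
rec_channels <- function(rec) setdiff(names(rec), "time")

#' @exportS3Method base::print
print.cpg_recording <- function(x, ...) {
  cat(sprintf(
    "<cpg_recording> %d channels x %.1f s @ %g Hz [%s]\n",
    length(rec_channels(x)), nrow(x) / rec_rate(x), rec_rate(x), rec_stage(x)
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse channel labels into segment and side
#'
#' @param labels Character vector of labels such as `"meso_L"`.
#' @return Tibble with columns `label`, `segment`, `side`.
#' @export
channel_info <- function(labels) {
  parts <- strsplit(labels, "_", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    abort(paste0("channel labels must look like '<segment>_<side>'; got: ",
                 paste(labels[bad], collapse = ", ")))
  }
  tibble::tibble(
    label = labels,
    segment = vapply(parts, `[`, "", 1),
    side = vapply(parts, `[`, "", 2)
  )
}

#' Read and write recordings as tab-separated text
#'
#' The on-disk layout is a TSV with header `time<TAB><label>...` plus a JSON
#' sidecar (`<path>.json`) holding the sampling rate, stage and metadata, so
#' a round trip preserves provenance. `read_recording()` works without the
#' sidecar by inferring the rate from the time column.
#'
#' @param path File path of the TSV.
#' @return `read_recording()` returns a `cpg_recording`.
#' @export
read_recording <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time" %in% names(df)) abort("format error: missing `time` column")
  if (anyNA(df)) abort("format error: ragged rows or missing values")
  meta <- list()
  stage <- "raw"
  rate <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rate <- side$rate
    stage <- side$stage %||% "raw"
    meta <- side$meta %||% list()
  }
  as_recording(df, rate = rate, stage = stage, meta = meta)
}

#' @rdname read_recording
#' @param rec Recording to write.
#' @export
write_recording <- function(rec, path) {
  utils::write.table(as.data.frame(rec), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  meta <- attr(rec, "meta") %||% list()
  # drop non-serialisable entries, keep plain vectors/matrices
  keep <- vapply(meta, function(x) is.numeric(x) || is.character(x) || is.logical(x), TRUE)
  jsonlite::write_json(
    list(rate = rec_rate(rec), stage = rec_stage(rec),
         labels = rec_channels(rec), meta = meta[keep]),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}
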