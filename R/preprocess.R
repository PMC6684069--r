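#' Preprocess a raw recording (DC removal, rectification, smoothing, downsampling)
#'
#' Replicates the standard extracellular preprocessing chain applied to nerve
#' recordings before phase or spectral analysis. Per channel, in order:
#' subtract the mean (DC removal), take the absolute value (full-wave
#' rectification), apply a centred moving average of width `smooth_window`,
#' low-pass filter at 0.8x the target Nyquist (anti-aliasing) and decimate to
#' `target_rate`, then subtract the mean again so the output is zero-mean.
#' The final mean re-subtraction makes the analytic-signal trajectory
#' encircle the origin, which the Poincare-section onset detector requires.
#'
#' @param raw A raw `cpg_recording` with rate >= `target_rate`; the ratio of
#'   rates must be an integer.
#' @param smooth_window Moving-average width in seconds (default 0.05 s:
#'   short against ~5 s burst cycles, long against the 30 Hz carrier).
#' @param target_rate Output sampling rate in Hz (default 200).
#' @return A `cpg_recording` with `stage = "preprocessed"` and
#'   `ceiling(n * target_rate / raw_rate)` samples per channel.
#' @examples
#' net <- make_architecture_network(7, strengths = list())
#' rec <- simulate_recording(net, simulation_params(duration = 20, seed = 1))
#' prep <- preprocess(rec)
#' rec_rate(prep)
#' @export
preprocess <- function(raw, smooth_window = 0.05, target_rate = 200) {
  if (rec_stage(raw) != "raw") abort("preprocess expects a raw recording")
  rate <- rec_rate(raw)
  if (target_rate > rate * (1 + 1e-9)) {
    abort("upsampling not supported: target_rate exceeds the recording rate")
  }
  if (smooth_window < 1 / rate) abort("smooth_window must be at least one sample")
  factor <- rate / target_rate
  if (abs(factor - round(factor)) > 1e-8) {
    abort("raw rate must be an integer multiple of target_rate")
  }
  factor <- round(factor)
  keep <- seq(1, nrow(raw), by = factor)
  w <- max(1L, round(smooth_window * rate))
  if (w %% 2 == 0) w <- w + 1L # centred window
  aa <- if (factor > 1) signal::butter(4, 0.8 * target_rate / rate) else NULL

  out <- purrr::map(rec_channels(raw), function(ch) {
    x <- raw[[ch]]
    x <- abs(x - mean(x))
    x <- moving_average(x, w)
    if (!is.null(aa)) x <- signal::filtfilt(aa, x)
    x <- x[keep]
    x - mean(x)
  })
  names(out) <- rec_channels(raw)
  as_recording(
    dplyr::bind_cols(tibble::tibble(time = raw$time[keep]), tibble::as_tibble(out)),
    rate = target_rate, stage = "preprocessed",
    meta = c(attr(raw, "meta") %||% list(),
             list(smooth_window = smooth_window))
  )
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
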