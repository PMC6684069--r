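#' Discrete-time analytic signal
#'
#' Builds `X = X_r + i X_i` where `X_i` is the discrete Hilbert transform of
#' the (zero-mean) input, via the one-sided FFT construction: positive
#' frequencies doubled, negative frequencies zeroed, DC and Nyquist kept.
#' The argument of `X` is the instantaneous phase of the rhythm.
#'
#' @param channel Real-valued zero-mean series (length >= 8).
#' @param rate Sampling rate in Hz.
#' @return A `cpg_analytic` object with fields `x_r`, `x_i`, `rate`.
#' @examples
#' t <- seq(0, 60, by = 1 / 200)
#' a <- analytic_signal(cos(2 * pi * 0.2 * t), 200)
#' @export
analytic_signal <- function(channel, rate) {
  if (any(!is.finite(channel))) abort("channel must be finite")
  if (length(channel) < 8) abort("channel too short for an analytic signal")
  if (all(channel == 0)) abort("no oscillation: channel is identically zero")
  n <- length(channel)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- fft(fft(channel) * h, inverse = TRUE) / n
  structure(list(x_r = Re(X), x_i = Im(X), rate = rate), class = "cpg_analytic")
}

#' @exportS3Method base::print
print.cpg_analytic <- function(x, ...) {
  cat(sprintf("<cpg_analytic> %d samples @ %g Hz\n", length(x$x_r), x$rate))
  invisible(x)
}

#' Poincare-section burst-onset detection
#'
#' Marks a burst onset each time the analytic-signal trajectory crosses a
#' fixed ray from the origin (`arg(X) = section_angle`) counter-clockwise.
#' Crossings are refined to sub-sample precision by linear interpolation of
#' the wrapped angle, and each onset carries the peak `|X|` of the following
#' cycle so small tonic units can later be filtered by amplitude. A margin at
#' both ends of the series is excluded to avoid Hilbert edge artifacts.
#'
#' @param a A `cpg_analytic`.
#' @param section_angle Angle of the section ray in radians (default 0: the
#'   positive real axis).
#' @param edge_exclude Seconds to ignore at each end (default 0.25 s).
#' @return A `cpg_onsets` tibble with columns `time`, `amplitude`,
#'   `retained` (all `TRUE` until [filter_small_units()] runs); attributes
#'   `rate`, `n_samples`, `section_angle`.
#' @export
detect_onsets <- function(a, section_angle = 0, edge_exclude = 0.25) {
  stopifnot(inherits(a, "cpg_analytic"))
  theta <- atan2(a$x_i, a$x_r)
  d <- wrap_pi(theta - section_angle)
  n <- length(d)
  k <- which(d[-n] < 0 & d[-1] >= 0 & (d[-1] - d[-n]) < pi)
  if (length(k) > 0) {
    # a crossing only counts after the trajectory has advanced at least half
    # a revolution since the last accepted one: rejects back-and-forth
    # wiggles of the section from residual carrier ripple or noise
    unwrapped <- cumsum(c(theta[1], wrap_pi(diff(theta))))
    keep <- logical(length(k))
    last_u <- -Inf
    for (i in seq_along(k)) {
      u <- unwrapped[k[i] + 1]
      if (u - last_u >= pi) {
        keep[i] <- TRUE
        last_u <- u
      }
    }
    k <- k[keep]
    frac <- -d[k] / (d[k + 1] - d[k])
    times <- (k - 1 + frac) / a$rate
    lo <- edge_exclude
    hi <- (n - 1) / a$rate - edge_exclude
    ok <- times >= lo & times <= hi
    k <- k[ok]
    times <- times[ok]
  } else {
    times <- numeric(0)
  }
  if (length(times) < 2) abort("rhythm too short: fewer than 2 section crossings")
  mod <- sqrt(a$x_r^2 + a$x_i^2)
  # amplitude of the cycle an onset starts: peak |X| until the trajectory
  # has completed one revolution (or the next crossing, whichever is first),
  # so a small-unit loop is scored by its own size, not by the next burst
  unwrapped <- cumsum(c(theta[1], wrap_pi(diff(theta))))
  amps <- vapply(seq_along(k), function(i) {
    j2 <- if (i < length(k)) k[i + 1] else n
    full <- which(unwrapped[k[i]:j2] - unwrapped[k[i]] >= 2 * pi)
    if (length(full) > 0) j2 <- k[i] + full[1] - 1L
    max(mod[k[i]:j2])
  }, numeric(1))
  structure(
    tibble::tibble(time = times, amplitude = amps, retained = TRUE),
    class = c("cpg_onsets", class(tibble::tibble())),
    rate = a$rate, n_samples = n, section_angle = section_angle
  )
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Filter small tonic units from detected onsets by amplitude clustering
#'
#' One-dimensional k-means with k = 2 on the onset amplitudes (deterministic
#' min/max centroid initialisation) separates large genuine bursts from small
#' tonic-unit events; only the large-centroid cluster is retained. If the
#' centroid ratio small/large exceeds `degeneracy_ratio` the two clusters are
#' considered one population (no small units present): all onsets stay
#' retained and a warning is emitted.
#'
#' @param onsets A `cpg_onsets` tibble with >= 4 onsets.
#' @param degeneracy_ratio Centroid-ratio threshold above which the split is
#'   declared degenerate (default 0.6).
#' @return The onsets with an updated `retained` mask; onset times are never
#'   altered.
#' @export
filter_small_units <- function(onsets, degeneracy_ratio = 0.6) {
  stopifnot(inherits(onsets, "cpg_onsets"))
  amps <- onsets$amplitude
  if (length(amps) < 4) abort("filter_small_units needs at least 4 onsets")
  if (diff(range(amps)) == 0) {
    warn("amplitude clustering degenerate: all onsets equal, none filtered")
    onsets$retained <- TRUE
    return(onsets)
  }
  km <- kmeans(amps, centers = matrix(c(min(amps), max(amps))))
  big <- which.max(km$centers)
  ratio <- min(km$centers) / max(km$centers)
  if (ratio > degeneracy_ratio) {
    warn(sprintf(
      "amplitude clustering degenerate (centroid ratio %.2f > %.2f): no small units filtered",
      ratio, degeneracy_ratio
    ))
    onsets$retained <- TRUE
  } else {
    onsets$retained <- km$cluster == big
  }
  onsets
}

#' Piecewise-linear instantaneous phase from burst onsets
#'
#' Between consecutive retained onsets k and k+1 the unwrapped phase is
#' `phi(t) = 2 pi (k + (t - t_k) / (t_{k+1} - t_k))`, so phase advances by
#' exactly one cycle per burst and equals `2 pi k` at the k-th onset.
#' Samples outside the span from first to last retained onset are `NA`.
#'
#' @param onsets A `cpg_onsets` with >= 2 retained onsets.
#' @param rate Output sampling rate in Hz (defaults to the onsets' rate).
#' @param n_samples Number of samples of the output grid (defaults to the
#'   analysed series length).
#' @return A `cpg_phase` tibble with columns `time`, `phi`; attributes
#'   `valid_span`, `rate`, `onsets`.
#' @examples
#' t <- seq(0, 60, by = 1 / 200)
#' a <- analytic_signal(cos(2 * pi * 0.2 * t), 200)
#' ph <- interpolate_phase(detect_onsets(a))
#' @export
interpolate_phase <- function(onsets, rate = NULL, n_samples = NULL) {
  stopifnot(inherits(onsets, "cpg_onsets"))
  rate <- rate %||% attr(onsets, "rate")
  n_samples <- n_samples %||% attr(onsets, "n_samples")
  tk <- onsets$time[onsets$retained]
  if (length(tk) < 2) abort("interpolate_phase needs at least 2 retained onsets")
  tt <- (seq_len(n_samples) - 1) / rate
  phi <- approx(x = tk, y = 2 * pi * (seq_along(tk) - 1), xout = tt, rule = 1)$y
  structure(
    tibble::tibble(time = tt, phi = phi),
    class = c("cpg_phase", class(tibble::tibble())),
    valid_span = range(tk), rate = rate, onsets = onsets
  )
}

#' Extract the instantaneous phase of one channel
#'
#' End-to-end wrapper: analytic signal, Poincare-section onset detection,
#' optional small-unit filtering and piecewise-linear phase interpolation.
#'
#' @param rec A preprocessed `cpg_recording`.
#' @param channel Channel label.
#' @param small_units `"auto"` (filter with the degeneracy guard, silencing
#'   the degenerate-split warning), `"on"` (filter, warn when degenerate) or
#'   `"off"`.
#' @param section_angle Poincare-section angle, radians.
#' @param edge_exclude Seconds excluded at each end of the series.
#' @return A `cpg_phase`.
#' @export
extract_phase <- function(rec, channel, small_units = c("auto", "on", "off"),
                          section_angle = 0, edge_exclude = 0.25) {
  small_units <- match.arg(small_units)
  if (!channel %in% rec_channels(rec)) {
    abort(sprintf("channel '%s' not found", channel))
  }
  a <- analytic_signal(rec[[channel]], rec_rate(rec))
  on <- detect_onsets(a, section_angle, edge_exclude)
  if (small_units == "on") {
    on <- filter_small_units(on)
  } else if (small_units == "auto" && nrow(on) >= 4) {
    on <- suppressWarnings(filter_small_units(on))
  }
  interpolate_phase(on)
}
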