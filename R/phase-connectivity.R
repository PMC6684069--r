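#' Mean resultant vector of a phase-difference series
#'
#' `R = |mean(exp(i * dphi))|`, the phase-locking value: 1 when every
#' difference is identical (mod 2 pi), near 0 for random differences. It is
#' invariant to adding a constant to all differences.
#'
#' @param phase_diff Phase differences in radians.
#' @return R in `[0, 1]`.
#' @examples
#' r_vector(rep(0.7, 1000)) # exactly 1
#' r_vector(c(0, pi / 2)) # sqrt(2)/2
#' @export
r_vector <- function(phase_diff) {
  if (length(phase_diff) == 0) abort("r_vector needs a non-empty series")
  if (any(!is.finite(phase_diff))) abort("phase differences must be finite")
  Mod(mean(exp(1i * phase_diff)))
}

#' Gliding-window R-vector between two phase series
#'
#' Computes the mean resultant vector of `phi1 - phi2` in a gliding window
#' over the common valid span of the two phases. Windows lie entirely inside
#' both valid spans.
#'
#' @param phi1,phi2 `cpg_phase` objects on the same sampling grid.
#' @param window Window length in seconds (default 15).
#' @param step Window step in seconds (default 1).
#' @return A `cpg_rvector` tibble with columns `time` (window centre) and
#'   `r`; attributes `window`, `step`, `rate`, `t_per_window` and the
#'   phase-difference series (`phase_diff`, a tibble `time`, `pd`).
#' @export
gliding_r <- function(phi1, phi2, window = 15, step = 1) {
  stopifnot(inherits(phi1, "cpg_phase"), inherits(phi2, "cpg_phase"))
  rate <- attr(phi1, "rate")
  if (!isTRUE(all.equal(rate, attr(phi2, "rate")))) {
    abort("phase series must share one sampling rate")
  }
  n <- min(nrow(phi1), nrow(phi2))
  pd <- phi1$phi[seq_len(n)] - phi2$phi[seq_len(n)]
  tt <- phi1$time[seq_len(n)]
  ok <- which(is.finite(pd))
  if (length(ok) == 0 || (tt[max(ok)] - tt[min(ok)]) < window) {
    abort("overlapping valid spans shorter than one window")
  }
  i0 <- min(ok); i1 <- max(ok)
  W <- round(window * rate)
  starts <- seq(i0, i1 - W + 1L, by = max(1L, round(step * rate)))
  cs <- cumsum(c(0, cos(pd[i0:i1])))
  sn <- cumsum(c(0, sin(pd[i0:i1])))
  rel <- starts - i0 + 1L
  r <- sqrt((cs[rel + W] - cs[rel])^2 + (sn[rel + W] - sn[rel])^2) / W
  structure(
    tibble::tibble(time = tt[starts] + window / 2, r = r),
    class = c("cpg_rvector", class(tibble::tibble())),
    window = window, step = step, rate = rate, t_per_window = W,
    phase_diff = tibble::tibble(time = tt[i0:i1], pd = pd[i0:i1])
  )
}

#' Detect phase-coupled intervals from a gliding R-vector trace
#'
#' Two criteria define a coupled interval: (1) the gliding-window R-vector
#' stays above `r_window_threshold` for at least `min_duration` seconds
#' (candidate intervals span the outer edges of the first and last
#' qualifying window; overlapping candidates are merged first); (2) the
#' R-vector of the whole candidate interval exceeds `interval_R_threshold`,
#' which rejects slowly drifting phase differences whose windowed R stays
#' high. Both thresholds were calibrated manually in the original analyses
#' and are exposed as arguments.
#'
#' @param rv A `cpg_rvector` from [gliding_r()].
#' @param phase_diff Tibble with `time`, `pd` (defaults to the series stored
#'   in `rv`).
#' @param r_window_threshold Window criterion threshold (default 0.8).
#' @param min_duration Minimal interval length in seconds (default 50,
#'   roughly 10 burst cycles).
#' @param interval_R_threshold Whole-interval criterion (default 0.3).
#' @return Tibble of accepted intervals: `start`, `end`, `interval_R`,
#'   `mean_phase_diff` (circular mean in `[0, 2 pi)`). Possibly empty.
#' @export
detect_coupled_intervals <- function(rv, phase_diff = NULL,
                                     r_window_threshold = 0.8,
                                     min_duration = 50,
                                     interval_R_threshold = 0.3) {
  stopifnot(inherits(rv, "cpg_rvector"))
  phase_diff <- phase_diff %||% attr(rv, "phase_diff")
  w <- attr(rv, "window")
  empty <- tibble::tibble(
    start = numeric(0), end = numeric(0),
    interval_R = numeric(0), mean_phase_diff = numeric(0)
  )
  above <- rv$r > r_window_threshold
  if (!any(above)) return(empty)
  runs <- rle(above)
  stops <- cumsum(runs$lengths)
  starts_i <- stops - runs$lengths + 1L
  cand <- tibble::tibble(
    start = rv$time[starts_i[runs$values]] - w / 2,
    end = rv$time[stops[runs$values]] + w / 2
  )
  # expansion by half a window can overlap adjacent runs: merge them
  cand <- merge_intervals(cand)
  out <- cand |>
    dplyr::mutate(
      stats = purrr::map2(.data$start, .data$end, function(s, e) {
        pd <- phase_diff$pd[phase_diff$time >= s & phase_diff$time <= e]
        z <- mean(exp(1i * pd))
        tibble::tibble(interval_R = Mod(z), mean_phase_diff = Arg(z) %% (2 * pi))
      })
    ) |>
    tidyr::unnest("stats") |>
    dplyr::filter(.data$end - .data$start >= min_duration,
                  .data$interval_R > interval_R_threshold)
  if (nrow(out) == 0) empty else out
}

merge_intervals <- function(iv) {
  iv <- dplyr::arrange(iv, .data$start)
  s <- iv$start; e <- iv$end
  keep_s <- s[1]; keep_e <- e[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (s[i] <= keep_e[length(keep_e)]) {
      keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
    } else {
      keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
    }
  }
  tibble::tibble(start = keep_s, end = keep_e)
}

#' Coupling likelihood: fraction of a recording spent phase-coupled
#'
#' The sum of the lengths of all coupled intervals divided by the total
#' recording length; recordings with no coupling count as 0.
#'
#' @param intervals Tibble with `start`, `end` (disjoint, inside
#'   `[0, total_time]`).
#' @param total_time Total recording length in seconds.
#' @return Value in `[0, 1]`.
#' @export
coupling_likelihood <- function(intervals, total_time) {
  if (nrow(intervals) == 0) return(0)
  iv <- dplyr::arrange(intervals, .data$start)
  if (any(iv$start < 0 | iv$end > total_time + 1e-9)) {
    abort("intervals must lie within [0, total_time]")
  }
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)] - 1e-9)) {
    abort("intervals must be disjoint")
  }
  sum(iv$end - iv$start) / total_time
}

#' Phase-connectivity report for one channel pair
#'
#' Full undirected analysis of one pair: phase extraction for both channels,
#' gliding R-vector, interval detection and coupling likelihood.
#'
#' @param rec Preprocessed `cpg_recording`.
#' @param ch1,ch2 Channel labels.
#' @param window,step,r_window_threshold,min_duration,interval_R_threshold
#'   Passed to [gliding_r()] / [detect_coupled_intervals()].
#' @param ... Passed to [extract_phase()].
#' @return A `cpg_coupling` object: list with `pair`, `intervals`,
#'   `likelihood`, `total_time`, `rvector`.
#' @export
phase_coupling <- function(rec, ch1, ch2, window = 15, step = 1,
                           r_window_threshold = 0.8, min_duration = 50,
                           interval_R_threshold = 0.3, ...) {
  phi1 <- extract_phase(rec, ch1, ...)
  phi2 <- extract_phase(rec, ch2, ...)
  rv <- gliding_r(phi1, phi2, window = window, step = step)
  iv <- detect_coupled_intervals(rv,
    r_window_threshold = r_window_threshold,
    min_duration = min_duration,
    interval_R_threshold = interval_R_threshold
  )
  total <- nrow(rec) / rec_rate(rec)
  structure(
    list(pair = c(ch1, ch2), intervals = iv,
         likelihood = coupling_likelihood(iv, total),
         total_time = total, rvector = rv),
    class = "cpg_coupling"
  )
}

#' @exportS3Method base::print
print.cpg_coupling <- function(x, ...) {
  cat(sprintf(
    "<cpg_coupling> %s ~ %s: %d coupled interval(s), likelihood %.3f over %.0f s\n",
    x$pair[1], x$pair[2], nrow(x$intervals), x$likelihood, x$total_time
  ))
  invisible(x)
}

#' Phase-connectivity analysis of all channel pairs
#'
#' @param rec Preprocessed `cpg_recording`.
#' @param pairs `"all"` or a 2-column matrix / list of label pairs.
#' @param ... Passed to [phase_coupling()].
#' @return Tibble with one row per unordered pair: `ch1`, `ch2`, `class`
#'   (e.g. `"meso-meso"`, `"meso-meta"`), `likelihood`, `n_intervals` and a
#'   `report` list-column of `cpg_coupling` objects.
#' @export
pc_report <- function(rec, pairs = "all", ...) {
  chans <- rec_channels(rec)
  if (identical(pairs, "all")) {
    pairs <- t(utils::combn(chans, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    rep <- phase_coupling(rec, pairs[i, 1], pairs[i, 2], ...)
    tibble::tibble(
      ch1 = pairs[i, 1], ch2 = pairs[i, 2],
      class = pair_class(pairs[i, 1], pairs[i, 2]),
      likelihood = rep$likelihood, n_intervals = nrow(rep$intervals),
      report = list(rep)
    )
  })
}

# connection class of an unordered channel pair, e.g. "meso-meso", "meso-meta"
pair_class <- function(ch1, ch2) {
  s1 <- channel_info(ch1)$segment
  s2 <- channel_info(ch2)$segment
  order_seg <- c("pro", "meso", "meta")
  segs <- c(s1, s2)
  idx <- match(segs, order_seg)
  if (!anyNA(idx)) segs <- segs[order(idx)] else segs <- sort(segs)
  paste(segs, collapse = "-")
}

#' Pairwise comparison of connection classes
#'
#' Welch two-sample t-tests between every pair of connection classes (e.g.
#' per-animal coupling likelihoods of meso-meso vs meso-meta connections).
#' Raw p-values are reported without multiplicity correction.
#'
#' @param values Data frame with columns `class` and `value` (one row per
#'   observation), or a named list of numeric vectors.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return Tibble with `class1`, `class2`, `t`, `p`, `significant`.
#' @export
compare_connection_classes <- function(values, alpha = 0.05) {
  if (is.list(values) && !is.data.frame(values)) {
    values <- purrr::imap_dfr(values, ~ tibble::tibble(class = .y, value = .x))
  }
  classes <- unique(values$class)
  sizes <- table(values$class)
  if (any(sizes < 2)) {
    abort(sprintf("every class needs >= 2 values (got: %s)",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  pairs <- utils::combn(classes, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    x <- values$value[values$class == pairs[1, i]]
    y <- values$value[values$class == pairs[2, i]]
    res <- tryCatch(
      t.test(x, y),
      error = function(e) {
        # zero-variance degenerate case
        if (isTRUE(all.equal(mean(x), mean(y)))) {
          list(statistic = 0, p.value = 1)
        } else {
          list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0)
        }
      }
    )
    tibble::tibble(
      class1 = pairs[1, i], class2 = pairs[2, i],
      t = unname(res$statistic), p = res$p.value,
      significant = res$p.value < alpha
    )
  })
}
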