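#' Empirical cross-spectral density (Welch estimator)
#'
#' Averaged cross-periodograms over Hann-tapered, half-overlapping, demeaned
#' segments, scaled as a one-sided density (units^2/Hz) and restricted to
#' `[fmin, fmax]`.
#'
#' @param rec Preprocessed `cpg_recording` (or any recording) with duration
#'   >= `2 * seg_len`.
#' @param fmin,fmax Frequency band in Hz (default 0.05-2 Hz, covering ~5 s
#'   burst cycles and their first harmonics).
#' @param seg_len Segment length in seconds (default 60).
#' @return A `cpg_csd`: list with `freq`, `S` (complex array p x p x nfreq),
#'   `n_avg` (segment count), `labels`, `rate`, `band`.
#' @export
empirical_csd <- function(rec, fmin = 0.05, fmax = 2, seg_len = 60) {
  rate <- rec_rate(rec)
  labels <- rec_channels(rec)
  X <- as.matrix(rec[labels])
  n <- nrow(X)
  L <- round(seg_len * rate)
  if (n < 2 * L) abort("recording too short: need at least 2 segments")
  hop <- L %/% 2
  starts <- seq(1, n - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  U <- sum(w^2)
  freqs <- (seq_len(L) - 1) * rate / L
  sel <- which(freqs >= fmin & freqs <= fmax & freqs > 0)
  p <- length(labels)
  S <- array(0 + 0i, dim = c(p, p, length(sel)))
  for (s in starts) {
    seg <- X[s:(s + L - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    Z <- mvfft(seg * w)[sel, , drop = FALSE]
    for (k in seq_along(sel)) {
      zz <- Z[k, ]
      S[, , k] <- S[, , k] + outer(zz, Conj(zz))
    }
  }
  S <- S * 2 / (length(starts) * U * rate) # one-sided density
  structure(
    list(freq = freqs[sel], S = S, n_avg = length(starts), labels = labels,
         rate = rate, band = c(fmin, fmax), seg_len = seg_len),
    class = "cpg_csd"
  )
}

#' @exportS3Method base::print
print.cpg_csd <- function(x, ...) {
  cat(sprintf(
    "<cpg_csd> %d channels, %d frequencies in [%.3g, %.3g] Hz, %s segments\n",
    length(x$labels), length(x$freq), min(x$freq), max(x$freq),
    ifelse(is.finite(x$n_avg), x$n_avg, "closed-form (no)")
  ))
  invisible(x)
}

#' Magnitude-squared coherence from a cross-spectral density
#'
#' @param csd A `cpg_csd`.
#' @return Array p x p x nfreq of `|S_ij|^2 / (S_ii S_jj)`.
#' @export
csd_coherence <- function(csd) {
  p <- length(csd$labels)
  coh <- array(0, dim = dim(csd$S))
  for (k in seq_along(csd$freq)) {
    d <- Re(diag(csd$S[, , k]))
    coh[, , k] <- Mod(csd$S[, , k])^2 / outer(d, d)
  }
  coh
}

#' Closed-form cross-spectral density of the linear oscillator network
#'
#' Each node is a stochastically driven damped oscillator
#' `z_i'' = -omega_i^2 z_i - gamma_i z_i' + sum_j A_ij z_j + noise`, i.e. the
#' linear coupled system `z' = (A + uB) z` written in second-order form with
#' coupling acting on the accelerations. The one-sided CSD of the observed
#' positions is `S(f) = 2 G H(f) Q H(f)^H G^T + s_obs I` with
#' `H(f) = (i 2 pi f I - M)^{-1}`; it is Hermitian and positive semidefinite
#' at every frequency, and exactly block-diagonal (zero off-diagonals) when
#' all coupling is zero.
#'
#' @param A Coupling matrix (1/s^2 scale; entry `[i, j]` = influence of node
#'   j's position on node i's acceleration).
#' @param damping Per-node damping gamma (1/s), recycled.
#' @param freq_hz Per-node natural frequency (Hz), recycled.
#' @param q Innovation noise power spectral density on the accelerations.
#' @param s_obs Flat observation-noise density (units^2/Hz).
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @return A `cpg_csd` with `n_avg = Inf` (no estimation noise).
#' @export
model_csd <- function(A, damping = 0.5, freq_hz = 0.2, q = 1, s_obs = 0,
                      freqs = seq(0.05, 2, by = 0.05)) {
  n <- nrow(A)
  gamma <- rep_len(damping, n)
  f0 <- rep_len(freq_hz, n)
  if (drift_max_re_cpp(gamma, f0, A) >= 0) {
    abort("model not stationary: drift matrix has eigenvalues with nonnegative real part")
  }
  S <- model_csd_cpp(gamma, f0, q, s_obs, A, freqs)
  labels <- rownames(A) %||% paste0("node_", seq_len(n))
  structure(
    list(freq = freqs, S = S, n_avg = Inf, labels = labels, rate = NA,
         band = range(freqs), seg_len = NA),
    class = "cpg_csd"
  )
}

#' Simulate a sample path of the linear oscillator network
#'
#' Exact discretisation of the linear stochastic differential equation used
#' by [model_csd()] (matrix-exponential transition and Van Loan innovation
#' covariance), so the simulation has no time-step bias at any sampling rate.
#' Observation noise is added so its one-sided density equals `s_obs`.
#'
#' @inheritParams model_csd
#' @param duration Length in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed.
#' @param labels Channel labels (default from `A` dimnames).
#' @param burn_in Seconds discarded so the path starts at stationarity
#'   (default 50).
#' @return A `cpg_recording` (stage `"preprocessed"`: the model observes the
#'   latent positions directly).
#' @export
simulate_linear_recording <- function(A, damping = 0.5, freq_hz = 0.2, q = 1,
                                      s_obs = 0, duration = 600, rate = 200,
                                      seed = 1, labels = NULL, burn_in = 50) {
  n <- nrow(A)
  gamma <- rep_len(damping, n)
  f0 <- rep_len(freq_hz, n)
  if (drift_max_re_cpp(gamma, f0, A) >= 0) {
    abort("model not stationary: drift matrix has eigenvalues with nonnegative real part")
  }
  M <- drift_matrix_cpp(gamma, f0, A)
  d <- 2 * n
  dt <- 1 / rate
  Qc <- matrix(0, d, d)
  diag(Qc)[seq(2, d, by = 2)] <- q
  # Van Loan: expm([[M, Qc], [0, -M']] dt) yields F and F %*% Qd
  blk <- rbind(cbind(M, Qc), cbind(matrix(0, d, d), -t(M)))
  E <- as.matrix(Matrix::expm(blk * dt))
  F_ <- E[1:d, 1:d]
  Qd <- E[1:d, (d + 1):(2 * d)] %*% t(F_)
  Qd <- (Qd + t(Qd)) / 2
  ev <- eigen(Qd, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  n_burn <- round(burn_in * rate)
  n_tot <- round(duration * rate) + n_burn
  set.seed(seed)
  path <- linear_path_cpp(F_, L, n_tot, numeric(d),
                          as.integer(seq(0, d - 1, by = 2)))
  path <- path[(n_burn + 1):n_tot, , drop = FALSE]
  if (s_obs > 0) {
    path <- path + matrix(rnorm(length(path), 0, sqrt(s_obs * rate / 2)),
                          nrow(path), ncol(path))
  }
  labels <- labels %||% rownames(A) %||% paste0("node_", seq_len(n))
  colnames(path) <- labels
  df <- dplyr::bind_cols(
    tibble::tibble(time = (seq_len(nrow(path)) - 1) * dt),
    tibble::as_tibble(as.data.frame(path))
  )
  as_recording(df, rate = rate, stage = "preprocessed",
               meta = list(seed = seed, A = A, damping = gamma,
                           freq_hz = f0, q = q, s_obs = s_obs))
}
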