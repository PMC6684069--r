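#' Simulation parameters for the synthetic burst generator
#'
#' Bundles and validates the knobs of the generator, which emulates
#' pilocarpine-induced depressor-motoneuron rhythms: per-channel bursting at
#' ~0.2 Hz cycle rates, weak directed coupling, optional small-amplitude
#' tonic-unit contamination and additive observation noise. Raw traces are
#' produced at 1000 Hz so the downsampling step of preprocessing is exercised.
#'
#' @param duration Recording length in seconds; `duration / dt` must be an
#'   integer count of samples.
#' @param dt Simulation step in seconds (raw sampling interval).
#' @param phase_noise_sd Phase diffusion, rad/sqrt(s).
#' @param burst_duty Fraction of each cycle spent bursting, in (0, 1).
#' @param burst_amplitude Burst envelope amplitude (arbitrary units).
#' @param carrier_freq Carrier oscillation inside bursts, Hz.
#' @param amplitude_jitter_sd Lognormal SD of per-burst amplitude jitter
#'   (0 disables).
#' @param small_unit_amplitude_ratio Amplitude of tonic small-unit events
#'   relative to `burst_amplitude`, in `[0, 1)`; 0 disables contamination.
#' @param small_unit_rate Small-unit event rate, events/s.
#' @param small_unit_kernel Width of the small-unit impulse kernel, seconds.
#' @param obs_noise_sd Additive Gaussian observation noise SD.
#' @param seed Integer seed; every simulation is reproducible given the seed.
#' @return A validated `cpg_sim_params` list.
#' @export
simulation_params <- function(duration = 600, dt = 0.001,
                              phase_noise_sd = 0.1,
                              burst_duty = 0.4, burst_amplitude = 1,
                              carrier_freq = 30, amplitude_jitter_sd = 0.1,
                              small_unit_amplitude_ratio = 0,
                              small_unit_rate = 1, small_unit_kernel = 0.05,
                              obs_noise_sd = 0.02, seed = 1L) {
  p <- list(
    duration = duration, dt = dt, phase_noise_sd = phase_noise_sd,
    burst_duty = burst_duty, burst_amplitude = burst_amplitude,
    carrier_freq = carrier_freq, amplitude_jitter_sd = amplitude_jitter_sd,
    small_unit_amplitude_ratio = small_unit_amplitude_ratio,
    small_unit_rate = small_unit_rate, small_unit_kernel = small_unit_kernel,
    obs_noise_sd = obs_noise_sd, seed = as.integer(seed)
  )
  num <- unlist(p[setdiff(names(p), "seed")])
  if (any(!is.finite(num))) abort("simulation parameters must be finite")
  if (dt <= 0) abort("dt must be > 0")
  if (burst_duty <= 0 || burst_duty >= 1) abort("burst_duty must lie in (0, 1)")
  if (small_unit_amplitude_ratio < 0 || small_unit_amplitude_ratio >= 1) {
    abort("small_unit_amplitude_ratio must lie in [0, 1)")
  }
  if (abs(duration / dt - round(duration / dt)) > 1e-8) {
    abort("duration / dt must be an integer sample count")
  }
  structure(p, class = "cpg_sim_params")
}

#' Simulate ground-truth phase trajectories
#'
#' Euler-Maruyama integration of weakly coupled phase oscillators,
#' `dphi_i = [2 pi f_i + sum_j K_ij sin(phi_j - phi_i)] dt + sigma dW`.
#' The sinusoidal (Kuramoto-type) coupling is the generator's ground truth;
#' downstream analyses never assume this functional form.
#'
#' @param network A `cpg_network` ground truth.
#' @param params A `cpg_sim_params`.
#' @return Tibble with `time` plus one unwrapped-phase column (radians) per
#'   node; the network rides along as attribute `network`.
#' @export
simulate_phases <- function(network, params) {
  stopifnot(inherits(network, "cpg_network"), inherits(params, "cpg_sim_params"))
  n_steps <- round(params$duration / params$dt)
  set.seed(params$seed)
  phi0 <- runif(length(network$labels), 0, 2 * pi)
  mat <- kuramoto_path_cpp(
    network$coupling, unname(network$intrinsic_freqs), params$dt, n_steps,
    params$phase_noise_sd, phi0
  )
  colnames(mat) <- network$labels
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(tibble::tibble(time = (seq_len(n_steps) - 1) * params$dt), out)
  attr(out, "network") <- network
  out
}

#' Render phase trajectories as a raw burst recording
#'
#' Each channel is a 30 Hz zero-mean carrier gated by a rectangular burst
#' envelope, active while the wrapped phase lies in the first `burst_duty`
#' fraction of the cycle, with optional per-burst lognormal amplitude jitter.
#' Small tonic units are Poisson events whose half-sine kernels gate the same
#' carrier at `small_unit_amplitude_ratio` of the burst amplitude. Gaussian
#' observation noise is added last. Ground-truth envelope onset times per
#' channel are stored in the recording metadata.
#'
#' @param phases Output of [simulate_phases()].
#' @param params A `cpg_sim_params`.
#' @return A raw `cpg_recording` at `1/dt` Hz.
#' @export
phases_to_recording <- function(phases, params) {
  stopifnot(inherits(params, "cpg_sim_params"))
  labels <- setdiff(names(phases), "time")
  phi <- as.matrix(phases[labels])
  if (any(!is.finite(phi))) abort("phases must be finite")
  t <- phases$time
  n <- length(t)
  rate <- 1 / params$dt
  carrier <- sin(2 * pi * params$carrier_freq * t)
  set.seed(params$seed + 1L)
  channels <- list()
  truth_onsets <- list()
  for (ch in labels) {
    p <- phi[, ch]
    cyc <- floor(p / (2 * pi))
    env <- (p - 2 * pi * cyc) / (2 * pi) < params$burst_duty
    # per-burst amplitude jitter, indexed by cycle number
    amp <- rep(params$burst_amplitude, n)
    if (params$amplitude_jitter_sd > 0) {
      idx <- cyc - min(cyc) + 1
      jit <- exp(rnorm(max(idx), 0, params$amplitude_jitter_sd))
      amp <- amp * jit[idx]
    }
    x <- amp * env * carrier
    if (params$small_unit_amplitude_ratio > 0) {
      x <- x + small_unit_trace(n, rate, params) * carrier
    }
    if (params$obs_noise_sd > 0) x <- x + rnorm(n, 0, params$obs_noise_sd)
    channels[[ch]] <- x
    truth_onsets[[ch]] <- phase_crossing_times(t, p)
  }
  as_recording(
    dplyr::bind_cols(tibble::tibble(time = t), tibble::as_tibble(channels)),
    rate = rate, stage = "raw",
    meta = list(
      seed = params$seed, params = unclass(params),
      network = attr(phases, "network"),
      truth_onsets = truth_onsets,
      truth_counts = lengths(truth_onsets)
    )
  )
}

# times where the unwrapped phase crosses integer multiples of 2*pi;
# cummax guards against tiny non-monotone excursions from phase noise
phase_crossing_times <- function(t, phi) {
  phi <- cummax(phi)
  lo <- ceiling(phi[1] / (2 * pi))
  hi <- floor(phi[length(phi)] / (2 * pi))
  if (hi < lo) return(numeric(0))
  approx(x = phi, y = t, xout = 2 * pi * (lo:hi), ties = "ordered")$y
}

# envelope of Poisson small-unit events: half-sine kernels of the given
# width, peak amplitude ratio * burst_amplitude
small_unit_trace <- function(n, rate, params) {
  lambda <- params$small_unit_rate * n / rate
  n_ev <- rpois(1, lambda)
  env <- numeric(n)
  if (n_ev == 0) return(env)
  ev <- sort(ceiling(runif(n_ev) * n))
  width <- max(2L, round(params$small_unit_kernel * rate))
  kern <- sin(pi * seq_len(width) / (width + 1))
  for (i in ev) {
    j <- i:min(n, i + width - 1L)
    env[j] <- pmax(env[j], kern[seq_along(j)])
  }
  env * params$small_unit_amplitude_ratio * params$burst_amplitude
}

#' Simulate a complete recording from a ground-truth network
#'
#' Convenience wrapper: [simulate_phases()] followed by
#' [phases_to_recording()].
#'
#' @inheritParams simulate_phases
#' @return A raw `cpg_recording` with ground truth in its metadata.
#' @examples
#' net <- make_architecture_network(2, strengths = list(intra = 0.5, inter = 0.3))
#' rec <- simulate_recording(net, simulation_params(duration = 60, seed = 7))
#' rec
#' @export
simulate_recording <- function(network, params) {
  phases_to_recording(simulate_phases(network, params), params)
}

#' Simulate a connected / cut-connective pair of trials
#'
#' Trial 1 is simulated from the full network; trial 2 from a copy whose
#' intersegmental coupling (ipsilateral and diagonal classes) is set to zero,
#' mimicking surgically cut connectives between ganglia. Intrasegmental
#' coupling in trial 2 may be rescaled by `compensation` to emulate the
#' compensatory increase seen after deafferenting the caudal segment.
#' The two trials use fresh seeds derived from `params$seed`.
#'
#' @inheritParams simulate_phases
#' @param compensation Multiplier applied to trial 2 intrasegmental coupling
#'   (optionally a named vector by segment, e.g. `c(meso = 2)`).
#' @return List with `trial1`, `trial2` (recordings) and `trial2_network`.
#' @export
make_cut_condition <- function(network, params, compensation = 1) {
  seg <- network_segments(network)
  if (length(unique(seg)) < 2) {
    abort("make_cut_condition needs a network with at least 2 segments")
  }
  cls <- edge_classes(network$labels)
  K2 <- network$coupling
  K2[cls %in% c("inter", "diag")] <- 0
  if (is.null(names(compensation))) {
    K2[cls == "intra"] <- K2[cls == "intra"] * compensation
  } else {
    for (s in names(compensation)) {
      sel <- cls == "intra" & outer(seg == s, seg == s, "&")
      K2[sel] <- K2[sel] * compensation[[s]]
    }
  }
  net2 <- new_network(network$labels, K2, unname(network$intrinsic_freqs),
                      network$sign, network$architecture_id)
  p1 <- params; p1$seed <- params$seed * 2L
  p2 <- params; p2$seed <- params$seed * 2L + 1L
  list(
    trial1 = simulate_recording(network, p1),
    trial2 = simulate_recording(net2, p2),
    trial2_network = net2
  )
}
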