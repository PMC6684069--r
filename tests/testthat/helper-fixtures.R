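# Shared fixtures, built in code. Generator settings mirror the package
# defaults (0.2 Hz cycles, 1000 Hz raw rate, 200 Hz preprocessed rate);
# durations are kept short where the property under test allows it.

fix_intra_network <- function(strength = 1) {
  make_architecture_network(6, 2, strengths = list(intra = strength))
}

# two uncoupled nodes with a frequency offset (the clearly uncoupled case)
fix_offset_network <- function(offset = 0.05) {
  mask <- architecture_mask(7, 2)
  new_net <- make_architecture_network(7, 2, strengths = list())
  new_net$intrinsic_freqs[] <- c(0.2, 0.2 + offset, 0.2, 0.2 + offset)
  new_net
}

fix_noise_free_params <- function(duration = 100, seed = 9) {
  simulation_params(
    duration = duration, seed = seed, phase_noise_sd = 0,
    obs_noise_sd = 0, amplitude_jitter_sd = 0
  )
}

# linear-model ground truth on the eight-shaped architecture (id 2)
fix_linear_A <- function(intra = 0.3, inter = 0.2) {
  mask <- architecture_mask(2, 2)
  A <- matrix(0, 4, 4, dimnames = dimnames(mask))
  cls <- cpgnet:::edge_classes(rownames(mask))
  A[mask & cls == "intra"] <- intra
  A[mask & cls == "inter"] <- inter
  A
}

# expected onset count for a perfectly periodic rhythm: number of points of
# the comb {t : t = offset + k * period} inside [lo, hi], with the offset
# measured from the detected onsets themselves (the Poincare section fixes
# an arbitrary but constant phase of the cycle)
comb_count <- function(onset_times, period, lo, hi) {
  offs <- onset_times %% period
  offset <- stats::median(offs)
  first <- offset + period * ceiling((lo - offset) / period)
  if (first > hi) return(0L)
  floor((hi - first) / period) + 1L
}
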