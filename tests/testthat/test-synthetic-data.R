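test_that("architecture edge sets have the documented sizes and classes", {
  # fully unconnected: no edges
  net7 <- make_architecture_network(7, 2, strengths = list(intra = 1))
  expect_true(all(net7$coupling == 0))
  # eight-shaped winner: contralateral within each segment + ipsilateral
  # between segments, bidirectional -> 8 directed edges
  net2 <- make_architecture_network(2, 2, strengths = list(intra = 0.3, inter = 0.2))
  expect_equal(sum(net2$coupling != 0), 8)
  cls <- cpgnet:::edge_classes(net2$labels)
  expect_true(all(net2$coupling[cls == "diag"] == 0))
  expect_equal(sum(net2$coupling[cls == "intra"] != 0), 4)
  expect_equal(sum(net2$coupling[cls == "inter"] != 0), 4)
  expect_equal(unique(net2$coupling[net2$coupling != 0]), c(0.3, 0.2),
               tolerance = 1e-12)
  # fully connected: every ordered pair
  net1 <- make_architecture_network(1, 2, strengths = list(intra = .1, inter = .1, diag = .1))
  expect_equal(sum(net1$coupling != 0), 12)
  expect_error(make_architecture_network(9, 2), "1-7")
  expect_error(make_architecture_network(5, 3), "1-4")
})

test_that("three-segment space builds on the two-segment winners", {
  n <- vapply(1:4, function(id) sum(architecture_mask(id, 3)), integer(1))
  # base: 6 intra + 8 adjacent ipsilateral; 2/3 add 4 pro-meta edges,
  # 4 adds the unidirectional meta->pro pair
  expect_equal(n, c(14L, 18L, 18L, 16L))
  m4 <- architecture_mask(4, 3)
  expect_true(m4["pro_L", "meta_L"] && m4["pro_R", "meta_R"])
  expect_false(m4["meta_L", "pro_L"] || m4["meta_R", "pro_R"])
})

test_that("inhibitory networks carry negative coupling", {
  net <- make_architecture_network(2, 2, strengths = list(intra = 0.3, inter = 0.2),
                                   sign = "inhibitory")
  expect_true(all(net$coupling[net$coupling != 0] < 0))
})

test_that("uncoupled noise-free phases advance exactly linearly", {
  net <- make_architecture_network(7, 2, strengths = list())
  p <- simulation_params(duration = 100, dt = 0.001, phase_noise_sd = 0, seed = 4)
  ph <- simulate_phases(net, p)
  for (ch in net$labels) {
    expect_equal(ph[[ch]] - ph[[ch]][1], 2 * pi * 0.2 * ph$time, tolerance = 1e-9)
  }
})

test_that("strong symmetric coupling locks two oscillators", {
  # independent verification target computed by integrating at dt/10 gives
  # circular variance < 0.05 over the second half; assert that bound
  net <- fix_intra_network(strength = 2)
  p <- simulation_params(duration = 500, dt = 0.001, phase_noise_sd = 0.1, seed = 21)
  ph <- simulate_phases(net, p)
  half <- ph$time > 250
  pd <- ph$meso_L[half] - ph$meso_R[half]
  circ_var <- 1 - Mod(mean(exp(1i * pd)))
  expect_lt(circ_var, 0.05)
})

test_that("simulations are deterministic given the seed", {
  net <- fix_intra_network()
  p <- simulation_params(duration = 30, seed = 12)
  r1 <- simulate_recording(net, p)
  r2 <- simulate_recording(net, p)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("recording rendering respects amplitude, noise and contamination switches", {
  net <- fix_intra_network()
  p <- simulation_params(duration = 30, seed = 3, burst_amplitude = 0,
                         obs_noise_sd = 0, small_unit_amplitude_ratio = 0)
  rec <- simulate_recording(net, p)
  expect_true(all(as.matrix(rec[rec_channels(rec)]) == 0))
})

test_that("noise-free burst count per channel matches the phase bookkeeping", {
  net <- make_architecture_network(7, 2, strengths = list())
  p <- fix_noise_free_params(duration = 100, seed = 5)
  rec <- simulate_recording(net, p)
  meta <- attr(rec, "meta")
  for (ch in rec_channels(rec)) {
    n_true <- meta$truth_counts[[ch]]
    expect_true(abs(n_true - floor(100 * 0.2)) <= 1)
    # envelope onsets exactly periodic with period 1/f
    expect_equal(diff(meta$truth_onsets[[ch]]), rep(5, n_true - 1),
                 tolerance = 1e-6)
  }
})

test_that("small-unit event count follows the Poisson rate", {
  net <- fix_intra_network()
  p <- simulation_params(duration = 100, seed = 7,
                         small_unit_amplitude_ratio = 0.15, small_unit_rate = 1)
  # count events directly from the contamination trace
  set.seed(p$seed + 1L)
  counts <- replicate(20, {
    env <- cpgnet:::small_unit_trace(100 * 1000, 1000, p)
    sum(diff(env > 0) == 1)
  })
  # lambda = 100: 3 sd band around the mean
  expect_true(abs(mean(counts) - 100) < 3 * sqrt(100) / sqrt(20))
})

test_that("cut-condition pair zeroes intersegmental coupling and can compensate", {
  net <- make_architecture_network(2, 2, strengths = list(intra = 0.5, inter = 0.3))
  p <- simulation_params(duration = 30, seed = 2)
  cut <- make_cut_condition(net, p)
  cls <- cpgnet:::edge_classes(net$labels)
  expect_true(all(cut$trial2_network$coupling[cls %in% c("inter", "diag")] == 0))
  expect_equal(sum(cut$trial2_network$coupling != 0), 4)
  cut2 <- make_cut_condition(net, p, compensation = c(meso = 2))
  K2 <- cut2$trial2_network$coupling
  seg <- cpgnet:::channel_info(net$labels)$segment
  meso <- seg == "meso"
  expect_equal(K2[meso, meso][K2[meso, meso] != 0], rep(1.0, 2))
  expect_error(make_cut_condition(fix_offset_network(), p), NA)
  one_seg <- make_architecture_network(6, 2, strengths = list(intra = 1),
                                       segments = c("meso", "meta"))
  # single-segment network must error
  mask1 <- matrix(c(0, 1, 1, 0), 2, 2)
  net1 <- cpgnet:::new_network(c("meso_L", "meso_R"),
                               matrix(c(0, .2, .2, 0), 2), c(0.2, 0.2),
                               "excitatory")
  expect_error(make_cut_condition(net1, p), "2 segments")
})

test_that("parameter validation rejects bad inputs", {
  expect_error(simulation_params(dt = 0), "dt")
  expect_error(simulation_params(burst_duty = 1), "burst_duty")
  expect_error(simulation_params(small_unit_amplitude_ratio = 1), "ratio")
  expect_error(simulation_params(duration = 10.0005), "integer")
  expect_error(simulation_params(phase_noise_sd = Inf), "finite")
})
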