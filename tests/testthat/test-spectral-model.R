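# a minimal hand-built fit object for testing BMS / strength summaries
fake_fit <- function(id, log_evidence, strengths = NULL, sig = c(1, 1, 1)) {
  mask <- architecture_mask(2, 2)
  labels <- rownames(mask)
  A <- matrix(0, 4, 4, dimnames = dimnames(mask))
  if (!is.null(strengths)) A[mask] <- strengths
  structure(
    list(architecture = list(id = id, labels = labels, mask = mask,
                             sign = "excitatory"),
         A_hat = A, log_evidence = log_evidence, n_cond = 1,
         node_params = tibble::tibble(label = labels, damping = 0.5,
                                      freq_hz = 0.2),
         noise_params = list(q = 1, s_obs = 0.01),
         data_sig = sig),
    class = "cpg_fit"
  )
}

test_that("duplicated channels have unit coherence everywhere", {
  set.seed(1)
  x <- rnorm(200 * 200)
  t <- seq_along(x) / 200 - 1 / 200
  rec <- as_recording(tibble::tibble(time = t, meso_L = x, meso_R = x),
                      stage = "raw")
  csd <- empirical_csd(rec, 0.05, 2, seg_len = 30)
  coh <- csd_coherence(csd)
  expect_equal(max(abs(coh[1, 2, ] - 1)), 0, tolerance = 1e-9)
})

test_that("independent white noise has near-zero coherence and a sine injects it", {
  set.seed(3)
  n <- 600 * 200
  t <- seq_len(n) / 200 - 1 / 200
  rec <- as_recording(tibble::tibble(time = t, meso_L = rnorm(n), meso_R = rnorm(n)))
  csd <- empirical_csd(rec, 0.05, 2, seg_len = 60)
  coh <- csd_coherence(csd)
  # Welch coherence bias for K independent segments is ~1/K
  expect_lt(mean(coh[1, 2, ]), 0.15)

  common <- sin(2 * pi * 0.2 * t)
  rec2 <- as_recording(tibble::tibble(time = t, meso_L = common + rnorm(n, 0, 0.5),
                                      meso_R = common + rnorm(n, 0, 0.5)))
  csd2 <- empirical_csd(rec2, 0.05, 2, seg_len = 60)
  coh2 <- csd_coherence(csd2)
  k02 <- which.min(abs(csd2$freq - 0.2))
  expect_gt(coh2[1, 2, k02], 0.9)

  short <- as_recording(tibble::tibble(time = t[1:2000], meso_L = rnorm(2000),
                                       meso_R = rnorm(2000)))
  expect_error(empirical_csd(short, seg_len = 60), "too short")
})

test_that("closed-form model CSD is Hermitian PSD with exact zeros when uncoupled", {
  A <- matrix(0, 3, 3)
  S <- model_csd(A, damping = 0.4, freq_hz = c(0.15, 0.2, 0.25), q = 1,
                 s_obs = 0.02)
  for (k in seq_along(S$freq)) {
    M <- S$S[, , k]
    expect_equal(M, Conj(t(M)), tolerance = 1e-12)
    expect_true(all(Re(eigen(M, only.values = TRUE)$values) >= -1e-12))
    expect_equal(max(Mod(M[upper.tri(M)])), 0, tolerance = 1e-15)
  }
  # coupling populates off-diagonals
  A2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  S2 <- model_csd(A2, 0.4, 0.2, 1, 0)
  expect_gt(max(Mod(S2$S[1, 2, ])), 0)
  # unstable drift must error
  expect_error(model_csd(matrix(c(0, 5, 5, 0), 2, 2), 0.1, 0.1, 1, 0),
               "not stationary")
})

test_that("exact-discretisation simulation matches the stationary variance", {
  A <- matrix(0, 1, 1, dimnames = list("meso_L", "meso_L"))
  rec <- simulate_linear_recording(A, damping = 2, freq_hz = 0.2, q = 1,
                                   s_obs = 0, duration = 2000, rate = 50,
                                   seed = 6)
  # stationary variance of a damped oscillator: q / (2 gamma omega^2)
  v_theory <- 1 / (2 * 2 * (2 * pi * 0.2)^2)
  expect_equal(var(rec$meso_L), v_theory, tolerance = 0.1)
  # seeded determinism
  rec2 <- simulate_linear_recording(A, 2, 0.2, 1, 0, duration = 10, rate = 50,
                                    seed = 8)
  rec3 <- simulate_linear_recording(A, 2, 0.2, 1, 0, duration = 10, rate = 50,
                                    seed = 8)
  expect_identical(rec2$meso_L, rec3$meso_L)
})

test_that("fitting degenerate zero-power spectra errors out", {
  fake_csd <- structure(
    list(freq = seq(0.05, 1, by = 0.05),
         S = array(0 + 0i, dim = c(2, 2, 20)), n_avg = 10,
         labels = c("meso_L", "meso_R"), rate = 200, band = c(0.05, 1),
         seg_len = 30),
    class = "cpg_csd"
  )
  expect_error(fit_model(fake_csd, matrix(TRUE, 2, 2,
                                          dimnames = list(c("meso_L", "meso_R"),
                                                          c("meso_L", "meso_R")))),
               "degenerate")
})

test_that("a short fit on linear data respects the mask and sign constraint", {
  A <- fix_linear_A(0.3, 0.2)
  rec <- simulate_linear_recording(A, 0.25, c(0.17, 0.2, 0.22, 0.25), 1, 0.01,
                                   duration = 200, rate = 200, seed = 4)
  csd <- empirical_csd(rec, 0.05, 2, seg_len = 25)
  fit <- fit_model(csd, 2, n_starts = 1, seed = 1)
  mask <- fit$architecture$mask
  expect_true(all(fit$A_hat[!mask] == 0))
  expect_true(all(fit$A_hat[mask] > 0)) # excitatory: minimal positive strength
  expect_true(is.finite(fit$log_evidence))
  ed <- tidy(fit)
  expect_equal(nrow(ed), 8)
  g <- glance(fit)
  expect_equal(g$n_connections, 8L)
})

test_that("BMS reproduces the two-model closed form and validates inputs", {
  f0 <- fake_fit("a", 0)
  f3 <- fake_fit("b", 3)
  out <- bms(list(f0, f3))
  expect_equal(out$posterior, c(1 / (1 + exp(3)), 1 / (1 + exp(-3))),
               tolerance = 1e-12)
  expect_equal(min(out$rel_log_evidence), 0)
  expect_equal(sum(out$posterior), 1, tolerance = 1e-12)
  expect_equal(bms_winner(out), "b")

  tie <- bms(list(fake_fit("a", 5), fake_fit("b", 5)))
  expect_equal(tie$posterior, c(0.5, 0.5), tolerance = 1e-12)

  expect_error(bms(list(f0)), "at least 2")
  expect_error(bms(list(f0, fake_fit("b", 1, sig = c(2, 2, 2)))),
               "identical data")
})

test_that("strength summaries symmetrise mirror pairs and normalise", {
  # meso intra pair 0.4 / 0.6 -> symmetrised 0.5; meta pair 1.0 / 1.0;
  # intersegmental 0.2 everywhere
  mask <- architecture_mask(2, 2)
  labels <- rownames(mask)
  A <- matrix(0, 4, 4, dimnames = dimnames(mask))
  A["meso_R", "meso_L"] <- 0.4 # meso_L -> meso_R
  A["meso_L", "meso_R"] <- 0.6
  A["meta_R", "meta_L"] <- 1.0
  A["meta_L", "meta_R"] <- 1.0
  A["meta_L", "meso_L"] <- 0.2
  A["meta_R", "meso_R"] <- 0.2
  A["meso_L", "meta_L"] <- 0.2
  A["meso_R", "meta_R"] <- 0.2
  fit <- fake_fit(2, 0)
  fit$A_hat <- A
  out <- summarize_strengths(list(fit))
  # mirror of meso_L->meso_R is meso_R->meso_L: averaged to 0.5, then
  # normalised by the maximum (meta-meta = 1)
  meso <- out$mean[out$class == "meso-meso"]
  expect_equal(meso, 0.5, tolerance = 1e-12)
  expect_equal(max(out$mean), 1)
  expect_equal(out$mean[out$class == "meso-meta"], c(0.2, 0.2),
               tolerance = 1e-12)

  ref <- summarize_strengths(list(fit), normalization = "reference_connection",
                             reference = "meso-meso")
  expect_equal(ref$mean[ref$class == "meso-meso"], 1)
  expect_equal(ref$mean[ref$class == "meta-meta"], 2)

  zero <- fake_fit(7, 0)
  expect_error(summarize_strengths(list(zero)), "nothing to normalize")
})

test_that("condition-change fits demand matching frequency grids", {
  A <- fix_linear_A()
  rec <- simulate_linear_recording(A, 0.25, 0.2, 1, 0.01, duration = 150,
                                   rate = 200, seed = 2)
  c1 <- empirical_csd(rec, 0.05, 2, seg_len = 25)
  c2 <- empirical_csd(rec, 0.05, 2, seg_len = 30)
  expect_error(fit_condition_change(c1, c2, 2), "mismatched")
})
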