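# helper to build phase/onset objects directly
make_onsets <- function(times, amplitudes = NULL, rate = 200,
                        n_samples = NULL) {
  structure(
    tibble::tibble(
      time = times,
      amplitude = amplitudes %||% rep(1, length(times)),
      retained = TRUE
    ),
    class = c("cpg_onsets", class(tibble::tibble())),
    rate = rate,
    n_samples = n_samples %||% (ceiling(max(times) * rate) + 1L),
    section_angle = 0
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("analytic signal of a tone is the complex exponential", {
  rate <- 200
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  a <- analytic_signal(cos(2 * pi * 0.2 * t), rate)
  interior <- t > 5 & t < 55
  expect_lt(max(abs(sqrt(a$x_r^2 + a$x_i^2)[interior] - 1)), 0.01)
  expect_lt(max(abs(a$x_i[interior] - sin(2 * pi * 0.2 * t[interior]))), 0.02)
})

test_that("analytic signal rejects degenerate input", {
  expect_error(analytic_signal(rep(0, 100), 200), "no oscillation")
  expect_error(analytic_signal(c(1, 2, NA, 4, 5, 6, 7, 8), 200), "finite")
  expect_error(analytic_signal(rnorm(4), 200), "short")
})

test_that("Hilbert transform matches an independent frequency-domain quadrature oracle", {
  # oracle: multiply the spectrum by -i*sign(f) and invert - a different
  # construction from the one-sided doubling used by the implementation
  quad_oracle <- function(x) {
    n <- length(x)
    X <- fft(x)
    sgn <- numeric(n)
    if (n %% 2 == 0) {
      sgn[2:(n / 2)] <- 1
      sgn[(n / 2 + 2):n] <- -1
    } else {
      sgn[2:((n + 1) / 2)] <- 1
      sgn[((n + 1) / 2 + 1):n] <- -1
    }
    Re(fft(X * (-1i) * sgn, inverse = TRUE) / n)
  }
  set.seed(11)
  for (n in c(256, 501)) {
    x <- rnorm(n)
    x <- x - mean(x)
    a <- analytic_signal(x, 100)
    expect_equal(a$x_i, quad_oracle(x), tolerance = 1e-10)
    expect_equal(a$x_r, x, tolerance = 1e-10)
    expect_lt(abs(mean(a$x_i)), 1e-10)
  }
})

test_that("Poincare crossings of a pure tone count its cycles", {
  rate <- 200
  t <- seq(0, 60 - 1 / rate, by = 1 / rate)
  a <- analytic_signal(cos(2 * pi * 0.2 * t), rate)
  on <- detect_onsets(a)
  expect_true(abs(nrow(on) - 12) <= 1)
  expect_lt(max(abs(diff(on$time) - 5)), 1 / rate)
})

test_that("onset amplitudes equal the cycle radius on a constant-amplitude circle", {
  rate <- 200
  t <- seq(0, 50 - 1 / rate, by = 1 / rate)
  a <- structure(list(x_r = cos(2 * pi * 0.2 * t),
                      x_i = sin(2 * pi * 0.2 * t), rate = rate),
                 class = "cpg_analytic")
  on <- detect_onsets(a)
  expect_equal(on$amplitude, rep(1, nrow(on)), tolerance = 1e-6)
})

test_that("too-short rhythms raise an error", {
  rate <- 200
  t <- seq(0, 3, by = 1 / rate)
  a <- analytic_signal(cos(2 * pi * 0.2 * t) + 0.001 * sin(t), rate)
  expect_error(detect_onsets(a), "too short")
})

test_that("noise-free generator cycles are recovered exactly (comb oracle)", {
  net <- fix_intra_network()
  p <- fix_noise_free_params(duration = 100, seed = 9)
  rec <- simulate_recording(net, p)
  prep <- preprocess(rec)
  for (ch in rec_channels(prep)) {
    on <- detect_onsets(analytic_signal(prep[[ch]], rec_rate(prep)))
    span_hi <- (attr(on, "n_samples") - 1) / attr(on, "rate") - 0.25
    expected <- comb_count(on$time, period = 5, lo = 0.25, hi = span_hi)
    expect_equal(nrow(on), expected)
    # detected onsets sit at a constant phase of the cycle
    expect_lt(stats::sd(on$time %% 5), 0.05)
  }
})

test_that("k-means amplitude filter separates clear clusters and flags degenerate ones", {
  on <- make_onsets(1:6, c(1, 1, 1, 10, 10, 10))
  out <- filter_small_units(on)
  expect_equal(out$retained, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$time, on$time) # times never altered

  on_eq <- make_onsets(1:5, rep(2, 5))
  expect_warning(out_eq <- filter_small_units(on_eq), "degenerate")
  expect_true(all(out_eq$retained))

  expect_error(filter_small_units(make_onsets(1:3)), "at least 4")
})

test_that("tonic small-unit stretches are filtered back to the true bursts", {
  # a minute of bursts followed by a minute of tonic small-unit activity:
  # the small loops cross the section too, and the amplitude clustering
  # must keep exactly the genuine bursts
  rate <- 200
  t <- seq(0, 120 - 1 / rate, by = 1 / rate)
  bump <- function(centers, width) {
    rowSums(vapply(centers, function(c0) exp(-(t - c0)^2 / (2 * width^2)),
                   numeric(length(t))))
  }
  big_t <- seq(2.5, 58, by = 5)
  small_t <- seq(61, 119, by = 2.5)
  x <- bump(big_t, 0.3) + 0.3 * bump(small_t, 0.2)
  x <- x - mean(x)
  on <- detect_onsets(analytic_signal(x, rate))
  expect_gt(nrow(on), length(big_t)) # contamination produces extra onsets
  out <- filter_small_units(on)
  kept <- out$time[out$retained]
  expect_equal(length(kept), length(big_t))
  expect_lt(max(abs(kept - big_t)), 0.5)
})

test_that("phase interpolation is piecewise linear with 2*pi per cycle", {
  on <- make_onsets(c(0, 1, 2), rate = 100, n_samples = 301)
  ph <- interpolate_phase(on)
  phi_at <- function(tt) ph$phi[match(TRUE, abs(ph$time - tt) < 1e-9)]
  expect_equal(phi_at(0.5), pi)
  expect_equal(phi_at(1.5), 3 * pi)
  expect_equal(phi_at(0), 0)
  expect_equal(phi_at(1), 2 * pi)
  expect_equal(phi_at(2), 4 * pi)

  on2 <- make_onsets(c(0, 2, 3), rate = 100, n_samples = 401)
  ph2 <- interpolate_phase(on2)
  phi2_at <- function(tt) ph2$phi[match(TRUE, abs(ph2$time - tt) < 1e-9)]
  expect_equal(phi2_at(1), pi)
  expect_equal(phi2_at(2.5), 3 * pi)

  # non-decreasing inside the valid span, NA outside
  d <- diff(ph2$phi[!is.na(ph2$phi)])
  expect_true(all(d >= -1e-12))
  expect_true(all(is.na(ph2$phi[ph2$time > 3])))
  expect_error(interpolate_phase(make_onsets(1)), "at least 2")
})

test_that("locked generator channels yield a tight extracted phase difference", {
  net <- fix_intra_network(strength = 1.5)
  p <- simulation_params(duration = 200, seed = 31)
  prep <- preprocess(simulate_recording(net, p))
  ph1 <- extract_phase(prep, "meso_L")
  ph2 <- extract_phase(prep, "meso_R")
  pd <- (ph1$phi - ph2$phi)
  pd <- pd[is.finite(pd)]
  circ_sd <- sqrt(-2 * log(Mod(mean(exp(1i * pd)))))
  expect_lt(circ_sd, 0.3)
})
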