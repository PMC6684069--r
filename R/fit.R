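#' Fit the linear oscillator network to an empirical cross-spectral density
#'
#' Fits the coupled model `z' = (A + uB) z` — realised as one damped
#' stochastic oscillator per node with coupling on the accelerations — to an
#' empirical CSD by maximising the spectral log joint: a Whittle
#' (complex-Wishart) likelihood over frequencies plus Gaussian priors on the
#' log-transformed parameters. Allowed coupling strengths are parameterised
#' as `sign * exp(theta)`, so a connection assumed present never vanishes
#' exactly and carries a minimal strength — which is also why superfluous
#' connections cost model evidence. The log model evidence is the Laplace
#' approximation at the optimum, which is what Bayesian model selection
#' ([bms()]) consumes.
#'
#' @param csd A `cpg_csd` from [empirical_csd()].
#' @param architecture An architecture id (resolved against the channel
#'   labels of `csd`) or a logical adjacency mask with the csd's labels as
#'   dimnames.
#' @param sign `"excitatory"` (positive coupling) or `"inhibitory"`.
#' @param priors Optional list overriding elements of [csd_priors()].
#' @param n_starts Number of optimisation starts (default 8); the best joint
#'   value is kept, ties broken by first found.
#' @param seed Seed for the start jitter.
#' @param max_freqs Cap on the number of fitted frequencies; denser grids
#'   are thinned evenly (default 80).
#' @param likelihood `"whittle"` (default: the complex-Wishart form
#'   `-K [log det S + tr(S^-1 S_emp)]` per frequency, which uses the full
#'   correlation structure of the averaged periodogram) or `"gaussian"`
#'   (independent Gaussian errors on the real and imaginary CSD entries with
#'   variance `S_ii S_jj / K`).
#' @return A `cpg_fit` with fitted coupling matrix `A_hat` (only masked
#'   entries nonzero, sign as requested), per-node `node_params`,
#'   `noise_params`, Laplace `log_evidence`, and `posterior_cov`.
#' @export
fit_model <- function(csd, architecture, sign = c("excitatory", "inhibitory"),
                      priors = NULL, n_starts = 8, seed = 1, max_freqs = 80,
                      likelihood = c("whittle", "gaussian")) {
  sign <- match.arg(sign)
  likelihood <- match.arg(likelihood)
  arch <- resolve_architecture(architecture, csd$labels, sign)
  prep <- prepare_csd_data(list(csd), max_freqs)
  pr <- build_priors(prep, arch, n_cond = 1, priors)
  spec <- c(prep, list(
    n_nodes = length(csd$labels),
    edge_to = arch$edge_to, edge_from = arch$edge_from,
    sign = if (sign == "excitatory") 1 else -1,
    u = 0, prior_mu = pr$mu, prior_sd = pr$sd,
    likelihood = if (likelihood == "whittle") 0L else 1L
  ))
  res <- optimize_joint(spec, pr, n_starts, seed)
  build_fit(res, arch, spec, prep, n_cond = 1)
}

#' Joint two-condition fit with condition-dependent coupling changes
#'
#' Fits both conditions jointly: condition 1 (`u = 0`) uses coupling `A`,
#' condition 2 (`u = 1`) uses `A + B`, with no prior information on which
#' connections change (`mask_B = mask_A`, change priors centred on "no
#' change"). Per-connection changes are reported as
#' `100 * ((A + B) / A - 1)`; absolute changes above `change_threshold`
#' percent are flagged reliable.
#'
#' @param csd1,csd2 `cpg_csd` objects of the two conditions on identical
#'   frequency grids.
#' @inheritParams fit_model
#' @param change_threshold Reliable-change threshold in percent (default 70).
#' @return A `cpg_fit` that additionally carries `B_hat`, `A2_hat`, a
#'   per-directed-edge `changes` tibble (`from`, `to`, `class`,
#'   `percent_change`, `reliable`) and a `changes_sym` tibble in which the
#'   two directions of each connection are combined before the percent
#'   change is computed (the per-side reporting convention).
#' @export
fit_condition_change <- function(csd1, csd2, architecture,
                                 sign = c("excitatory", "inhibitory"),
                                 priors = NULL, n_starts = 8, seed = 1,
                                 max_freqs = 80, change_threshold = 70,
                                 likelihood = c("whittle", "gaussian")) {
  sign <- match.arg(sign)
  likelihood <- match.arg(likelihood)
  if (length(csd1$freq) != length(csd2$freq) ||
      any(abs(csd1$freq - csd2$freq) > 1e-9)) {
    abort("mismatched frequency grids between conditions")
  }
  arch <- resolve_architecture(architecture, csd1$labels, sign)
  prep <- prepare_csd_data(list(csd1, csd2), max_freqs)
  pr <- build_priors(prep, arch, n_cond = 2, priors)
  spec <- c(prep, list(
    n_nodes = length(csd1$labels),
    edge_to = arch$edge_to, edge_from = arch$edge_from,
    sign = if (sign == "excitatory") 1 else -1,
    u = c(0, 1), prior_mu = pr$mu, prior_sd = pr$sd,
    likelihood = if (likelihood == "whittle") 0L else 1L
  ))
  res <- optimize_joint(spec, pr, n_starts, seed)
  fit <- build_fit(res, arch, spec, prep, n_cond = 2)
  m <- length(arch$edge_to)
  n <- length(arch$labels)
  delta <- res$theta[2 * n + 2 + m + seq_len(m)]
  A2 <- fit$A_hat
  A2[cbind(arch$edge_to + 1, arch$edge_from + 1)] <-
    fit$A_hat[cbind(arch$edge_to + 1, arch$edge_from + 1)] * exp(delta)
  pct <- 100 * (exp(delta) - 1)
  fit$A2_hat <- A2
  fit$B_hat <- A2 - fit$A_hat
  from_l <- arch$labels[arch$edge_from + 1]
  to_l <- arch$labels[arch$edge_to + 1]
  fit$changes <- tibble::tibble(
    from = from_l, to = to_l,
    class = purrr::map2_chr(from_l, to_l, pair_class),
    percent_change = pct,
    reliable = abs(pct) > change_threshold
  )
  # symmetrised per-connection changes: both directions of a connection
  # measure one pathway, so strengths are summed per unordered node pair
  # before computing the percent change (the convention used for reporting
  # connectivity changes per body side)
  key <- purrr::map2_chr(from_l, to_l, ~ paste(sort(c(.x, .y)), collapse = " <-> "))
  a1 <- abs(fit$A_hat[cbind(arch$edge_to + 1, arch$edge_from + 1)])
  a2 <- abs(A2[cbind(arch$edge_to + 1, arch$edge_from + 1)])
  fit$changes_sym <- tibble::tibble(
    connection = key,
    class = purrr::map2_chr(from_l, to_l, pair_class),
    a1 = a1, a2 = a2
  ) |>
    dplyr::group_by(.data$connection, .data$class) |>
    dplyr::summarise(percent_change = 100 * (sum(.data$a2) / sum(.data$a1) - 1),
                     .groups = "drop") |>
    dplyr::mutate(reliable = abs(.data$percent_change) > change_threshold)
  fit
}

# ---- internals ---------------------------------------------------------

resolve_architecture <- function(architecture, labels, sign) {
  if (is.matrix(architecture)) {
    mask <- architecture
    stopifnot(!is.null(rownames(mask)), all(labels %in% rownames(mask)))
    mask <- mask[labels, labels]
    id <- "custom"
  } else {
    segs <- unique(channel_info(labels)$segment)
    canonical <- intersect(c("pro", "meso", "meta"), segs)
    if (length(canonical) == length(segs)) segs <- canonical
    full <- architecture_mask(architecture, length(segs), segs)
    if (!all(labels %in% rownames(full))) {
      abort("csd labels do not match the architecture's node labels")
    }
    mask <- full[labels, labels]
    id <- architecture
  }
  diag(mask) <- FALSE
  idx <- which(mask, arr.ind = TRUE)
  list(id = id, labels = labels, mask = mask, sign = sign,
       edge_to = as.integer(idx[, 1] - 1L), edge_from = as.integer(idx[, 2] - 1L))
}

# thin frequencies, assemble S cubes and residual-variance cubes
prepare_csd_data <- function(csds, max_freqs) {
  freqs <- csds[[1]]$freq
  keep <- if (length(freqs) > max_freqs) {
    unique(round(seq(1, length(freqs), length.out = max_freqs)))
  } else {
    seq_along(freqs)
  }
  S <- list()
  V <- list()
  Ks <- numeric(length(csds))
  for (c in seq_along(csds)) {
    csd <- csds[[c]]
    K <- if (is.finite(csd$n_avg)) csd$n_avg else 1
    Sc <- csd$S[, , keep, drop = FALSE]
    p <- dim(Sc)[1]
    pow <- vapply(seq_len(dim(Sc)[3]), function(k) Re(diag(Sc[, , k])),
                  numeric(p))
    if (max(pow) <= 0 || !all(is.finite(pow))) {
      abort("degenerate cross-spectrum: no signal power")
    }
    Vc <- array(0, dim = dim(Sc))
    floorv <- (1e-6 * max(pow))^2
    for (k in seq_len(dim(Sc)[3])) {
      d <- Re(diag(Sc[, , k]))
      Vc[, , k] <- pmax(outer(d, d) / K, floorv)
    }
    S[[c]] <- Sc
    V[[c]] <- Vc
    Ks[c] <- K
  }
  list(freqs = freqs[keep], S = S, V = V, K = Ks)
}

# default Gaussian priors on the transformed parameter vector. The edge
# prior is deliberately tight around a genuine default strength
# (0.4 * gamma0): an allowed connection cannot be silently zeroed out, so
# superfluous connections cost model evidence on data that lack them -- the
# mechanism behind architecture discrimination.
csd_priors <- function() {
  list(gamma0 = 0.5, sd_log_gamma = 0.7, sd_log_f = 0.3,
       sd_log_q = 2, sd_log_sobs = 2,
       edge_frac = 0.4, sd_edge = 0.5, sd_delta = 2)
}

build_priors <- function(prep, arch, n_cond, overrides = NULL) {
  pr <- utils::modifyList(csd_priors(), overrides %||% list())
  S1 <- prep$S[[1]]
  p <- dim(S1)[1]
  diagpow <- vapply(seq_len(dim(S1)[3]), function(k) mean(Re(diag(S1[, , k]))),
                    numeric(1))
  f_peak <- prep$freqs[which.max(diagpow)]
  p_peak <- max(diagpow)
  w0 <- 2 * pi * f_peak
  q0 <- max(p_peak * pr$gamma0^2 * w0^2 / 2, 1e-12)
  m <- length(arch$edge_to)
  mu <- c(rep(log(pr$gamma0), p), rep(log(f_peak), p),
          log(q0), log(max(p_peak / 100, 1e-12)),
          rep(log(pr$edge_frac * pr$gamma0), m))
  sd <- c(rep(pr$sd_log_gamma, p), rep(pr$sd_log_f, p),
          pr$sd_log_q, pr$sd_log_sobs, rep(pr$sd_edge, m))
  if (n_cond == 2) {
    mu <- c(mu, rep(0, m))
    sd <- c(sd, rep(pr$sd_delta, m))
  }
  list(mu = mu, sd = sd, f_peak = f_peak, p_peak = p_peak)
}

optimize_joint <- function(spec, pr, n_starts, seed) {
  fn <- function(th) csd_nlj_cpp(th, spec)
  d <- length(pr$mu)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- pr$mu
    if (s > 1) start <- start + rnorm(d, 0, 0.4 * pr$sd)
    res <- tryCatch(
      nlminb(start, fn,
             control = list(iter.max = 500, eval.max = 10000, rel.tol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$objective) || res$objective >= 1e7) next
    if (is.null(best) || res$objective < best$objective - 1e-9) best <- res
  }
  if (is.null(best)) {
    abort("optimizer failed to converge from any start (all runs unstable or non-finite)")
  }
  H <- optimHess(best$par, fn)
  list(theta = best$par, objective = best$objective, hessian = H,
       convergence = best$convergence, d = d)
}

build_fit <- function(res, arch, spec, prep, n_cond) {
  n <- length(arch$labels)
  m <- length(arch$edge_to)
  theta <- res$theta
  gamma <- exp(theta[seq_len(n)])
  f0 <- exp(theta[n + seq_len(n)])
  q <- exp(theta[2 * n + 1])
  s_obs <- exp(theta[2 * n + 2])
  A <- matrix(0, n, n, dimnames = list(arch$labels, arch$labels))
  if (m > 0) {
    A[cbind(arch$edge_to + 1, arch$edge_from + 1)] <-
      spec$sign * exp(theta[2 * n + 2 + seq_len(m)])
  }
  ev <- eigen((res$hessian + t(res$hessian)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-8 * max(abs(ev$values), 1))
  post_cov <- ev$vectors %*% diag(1 / vals, res$d) %*% t(ev$vectors)
  log_evidence <- -res$objective + 0.5 * res$d * log(2 * pi) -
    0.5 * sum(log(vals))
  structure(
    list(
      architecture = arch[c("id", "labels", "mask", "sign")],
      theta = theta,
      A_hat = A,
      node_params = tibble::tibble(label = arch$labels, damping = gamma,
                                   freq_hz = f0),
      noise_params = list(q = q, s_obs = s_obs),
      log_evidence = log_evidence,
      posterior_cov = post_cov,
      objective = res$objective,
      convergence = res$convergence,
      n_cond = n_cond,
      data_sig = data_signature(prep)
    ),
    class = "cpg_fit"
  )
}

data_signature <- function(prep) {
  c(length(prep$freqs), length(prep$S),
    round(sum(vapply(prep$S, function(s) sum(Re(s)), numeric(1))), 6))
}

#' @exportS3Method base::print
print.cpg_fit <- function(x, ...) {
  cat(sprintf(
    "<cpg_fit> architecture %s (%s), %d nodes, %d connections, log evidence %.2f\n",
    x$architecture$id, x$architecture$sign, length(x$architecture$labels),
    sum(x$architecture$mask), x$log_evidence
  ))
  invisible(x)
}
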