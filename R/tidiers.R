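#' Tidy a fitted spectral model
#'
#' @param x A `cpg_fit`.
#' @param what `"edges"` (fitted coupling strengths per directed connection),
#'   `"changes"` (condition changes, two-condition fits only) or `"nodes"`
#'   (per-node damping and natural frequency).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cpg_fit <- function(x, what = c("edges", "changes", "nodes"), ...) {
  what <- match.arg(what)
  if (what == "nodes") return(x$node_params)
  if (what == "changes") {
    if (is.null(x$changes)) abort("no condition changes: this is a single-condition fit")
    return(x$changes)
  }
  idx <- which(x$architecture$mask, arr.ind = TRUE)
  labels <- x$architecture$labels
  from <- labels[idx[, 2]]
  to <- labels[idx[, 1]]
  tibble::tibble(
    from = from, to = to,
    class = purrr::map2_chr(from, to, pair_class),
    strength = x$A_hat[idx]
  )
}

#' @rdname tidy.cpg_fit
#' @export
glance.cpg_fit <- function(x, ...) {
  tibble::tibble(
    architecture = as.character(x$architecture$id),
    sign = x$architecture$sign,
    n_nodes = length(x$architecture$labels),
    n_connections = sum(x$architecture$mask),
    n_conditions = x$n_cond,
    log_evidence = x$log_evidence,
    converged = x$convergence == 0
  )
}

#' Tidy Bayesian model selection results
#' @param x A `cpg_bms`.
#' @param ... Unused.
#' @export
tidy.cpg_bms <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.cpg_bms
#' @export
glance.cpg_bms <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x), winner = bms_winner(x),
    winner_posterior = max(x$posterior)
  )
}

#' Tidy a phase-coupling report
#'
#' @param x A `cpg_coupling`.
#' @param ... Unused.
#' @return `tidy()`: the coupled intervals; `glance()`: one-row summary with
#'   the coupling likelihood.
#' @export
tidy.cpg_coupling <- function(x, ...) x$intervals

#' @rdname tidy.cpg_coupling
#' @export
glance.cpg_coupling <- function(x, ...) {
  tibble::tibble(
    ch1 = x$pair[1], ch2 = x$pair[2],
    class = pair_class(x$pair[1], x$pair[2]),
    n_intervals = nrow(x$intervals),
    coupled_time = sum(x$intervals$end - x$intervals$start),
    total_time = x$total_time,
    likelihood = x$likelihood
  )
}
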