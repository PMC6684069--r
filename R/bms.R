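#' Bayesian model selection over fitted architectures
#'
#' Compares candidate coupling architectures by their Laplace log evidences.
#' Relative log evidences are displayed against the least probable model;
#' posterior model probabilities follow from equal model priors (softmax of
#' the log evidences), which for two models reduces to the closed form
#' `p = 1 / (1 + exp(-log B))` with `log B` the log Bayes factor.
#'
#' @param fits List of `cpg_fit` objects fitted to the same data.
#' @return A `cpg_bms`: tibble with `model_id`, `log_evidence`,
#'   `rel_log_evidence`, `posterior`; the winning id is attribute `winner`.
#' @examples
#' # two models with log evidences 0 and 3: winner posterior 1/(1+exp(-3))
#' @export
bms <- function(fits) {
  if (length(fits) < 2) abort("bms needs at least 2 fitted models")
  sigs <- purrr::map(fits, "data_sig")
  if (!all(vapply(sigs[-1], identical, TRUE, sigs[[1]]))) {
    abort("all fits must be estimated on identical data")
  }
  le <- vapply(fits, function(f) f$log_evidence, numeric(1))
  ids <- vapply(fits, function(f) as.character(f$architecture$id), character(1))
  rel <- le - min(le)
  post <- exp(le - max(le))
  post <- post / sum(post)
  out <- tibble::tibble(
    model_id = ids, log_evidence = le,
    rel_log_evidence = rel, posterior = post
  )
  structure(out,
    class = c("cpg_bms", class(tibble::tibble())),
    winner = ids[which.max(le)]
  )
}

#' @rdname bms
#' @param x A `cpg_bms`.
#' @export
bms_winner <- function(x) attr(x, "winner")

#' @exportS3Method base::print
print.cpg_bms <- function(x, ...) {
  cat(sprintf("<cpg_bms> %d models, winner: %s\n", nrow(x), bms_winner(x)))
  NextMethod()
}
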