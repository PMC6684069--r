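#' Crop a recording to a time span
#'
#' @param rec A `cpg_recording`.
#' @param start,end Span in seconds (inclusive).
#' @return A `cpg_recording` over the span, time re-zeroed.
#' @export
crop_recording <- function(rec, start, end) {
  df <- dplyr::filter(tibble::as_tibble(rec),
                      .data$time >= start - 1e-9, .data$time <= end + 1e-9)
  df$time <- df$time - df$time[1]
  as_recording(df, rate = rec_rate(rec), stage = rec_stage(rec),
               meta = attr(rec, "meta") %||% list())
}

#' Select analysis epochs from a recording
#'
#' `"gliding"` mode places `n_epochs` spans of `epoch_len` seconds evenly
#' across the recording (deterministic, first at 0, last ending at the
#' recording end). `"biased"` mode draws epochs from within the coupled
#' intervals detected by the phase-connectivity analysis, longest interval
#' first, trimming each to `epoch_len`.
#'
#' @param rec A `cpg_recording`.
#' @param mode `"gliding"` or `"biased"`.
#' @param pc_reports For `"biased"`: the tibble from [pc_report()], a list of
#'   `cpg_coupling` objects, or an intervals tibble (`start`, `end`).
#' @param epoch_len Epoch length in seconds (default 50).
#' @param n_epochs Number of epochs (default 5).
#' @return Tibble with `start`, `end` (possibly empty in biased mode, with a
#'   warning, when no coupled interval exists).
#' @export
select_epochs <- function(rec, mode = c("gliding", "biased"),
                          pc_reports = NULL, epoch_len = 50, n_epochs = 5) {
  mode <- match.arg(mode)
  dur <- nrow(rec) / rec_rate(rec)
  if (epoch_len > dur) abort("epoch_len exceeds the recording duration")
  if (mode == "gliding") {
    starts <- unique(seq(0, dur - epoch_len, length.out = n_epochs))
    return(tibble::tibble(start = starts, end = starts + epoch_len))
  }
  if (is.null(pc_reports)) abort("biased mode requires pc_reports")
  iv <- gather_intervals(pc_reports)
  iv <- iv[iv$end - iv$start >= epoch_len, , drop = FALSE]
  if (nrow(iv) == 0) {
    warn("no coupled interval long enough for an epoch: returning no epochs")
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  iv <- iv[order(iv$end - iv$start, decreasing = TRUE), ]
  out <- list()
  for (i in seq_len(nrow(iv))) {
    k <- floor((iv$end[i] - iv$start[i]) / epoch_len)
    s <- iv$start[i] + (seq_len(k) - 1) * epoch_len
    out[[i]] <- tibble::tibble(start = s, end = s + epoch_len)
    if (sum(vapply(out, nrow, integer(1))) >= n_epochs) break
  }
  utils::head(dplyr::distinct(dplyr::bind_rows(out)), n_epochs)
}

gather_intervals <- function(pc_reports) {
  if (is.data.frame(pc_reports) && "report" %in% names(pc_reports)) {
    iv <- purrr::map_dfr(pc_reports$report, "intervals")
  } else if (is.data.frame(pc_reports)) {
    iv <- pc_reports
  } else {
    iv <- purrr::map_dfr(pc_reports, "intervals")
  }
  if (nrow(iv) == 0) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  merge_intervals(iv[c("start", "end")])
}

#' Run an end-to-end connectivity experiment
#'
#' Orchestrates the full workflow on a simulated or stored recording:
#' preprocessing, per-channel phase extraction, pairwise phase-connectivity,
#' epoch selection, spectral model fitting over a model space, Bayesian model
#' selection (per epoch, and aggregated by summing log evidences over
#' epochs) and strength summaries; or, in `condition_change` mode, the
#' two-condition connected/cut-connective analysis. Deterministic given
#' `config$seed`.
#'
#' @param config Named list (or path to a JSON file). Fields:
#'   `mode` (`"pc_only"`, `"dcm_biased"`, `"dcm_gliding"`,
#'   `"condition_change"`); `seed`; either `recording` (TSV path) or
#'   `simulation` (list with `architecture_id`, `n_segments`, `strengths`,
#'   `intrinsic_freqs`, `sign`, and [simulation_params()] overrides);
#'   optional `epoch_len` (50), `n_epochs` (5), `model_space`, `band`
#'   (c(0.05, 2)), `smooth_window` (0.05), `window`/`r_window_threshold`/
#'   `min_duration`/`interval_R_threshold`, `n_starts` (8),
#'   `compensation` (condition_change).
#' @return A `cpg_report` list with elements depending on the mode, plus
#'   `provenance`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(mode = "pc_only", seed = 1L, epoch_len = 50, n_epochs = 5,
         band = c(0.05, 2), smooth_window = 0.05, window = 15, step = 1,
         r_window_threshold = 0.8, min_duration = 50,
         interval_R_threshold = 0.3, n_starts = 8, compensation = 1,
         sign = "excitatory"),
    config
  )
  mode <- match.arg(cfg$mode, c("pc_only", "dcm_biased", "dcm_gliding",
                                "condition_change"))
  report <- list(config = cfg, mode = mode)

  sim <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- build_simulation(cfg)
  }

  if (mode == "condition_change") {
    if (is.null(sim)) abort("condition_change mode requires a simulation spec")
    trials <- make_cut_condition(sim$network, sim$params,
                                 compensation = cfg$compensation)
    prep1 <- preprocess(trials$trial1, cfg$smooth_window)
    prep2 <- preprocess(trials$trial2, cfg$smooth_window)
    seg <- cfg$seg_len %||% 60
    csd1 <- empirical_csd(prep1, cfg$band[1], cfg$band[2], seg)
    csd2 <- empirical_csd(prep2, cfg$band[1], cfg$band[2], seg)
    fit <- fit_condition_change(csd1, csd2,
      architecture = cfg$architecture %||% sim$network$architecture_id,
      sign = cfg$sign, n_starts = cfg$n_starts, seed = cfg$seed
    )
    report$condition <- fit
    report$changes <- fit$changes
    return(finish_report(report, cfg))
  }

  rec <- if (!is.null(sim)) {
    simulate_recording(sim$network, sim$params)
  } else if (!is.null(cfg$recording)) {
    read_recording(cfg$recording)
  } else {
    abort("config needs either `recording` or `simulation`")
  }
  prep <- preprocess(rec, cfg$smooth_window)
  pc <- pc_report(prep,
    window = cfg$window, step = cfg$step,
    r_window_threshold = cfg$r_window_threshold,
    min_duration = cfg$min_duration,
    interval_R_threshold = cfg$interval_R_threshold
  )
  report$pc <- dplyr::select(pc, -"report")
  report$pc_full <- pc
  if (mode == "pc_only") return(finish_report(report, cfg))

  epochs <- select_epochs(prep,
    mode = if (mode == "dcm_biased") "biased" else "gliding",
    pc_reports = pc, epoch_len = cfg$epoch_len, n_epochs = cfg$n_epochs
  )
  report$epochs <- epochs
  if (nrow(epochs) == 0) return(finish_report(report, cfg))

  n_seg_rec <- length(unique(channel_info(rec_channels(prep))$segment))
  space <- cfg$model_space %||% (if (n_seg_rec == 2) 1:7 else 1:4)
  seg_len <- cfg$seg_len %||% (cfg$epoch_len / 4)
  fits <- purrr::map(seq_len(nrow(epochs)), function(i) {
    csd <- empirical_csd(crop_recording(prep, epochs$start[i], epochs$end[i]),
                         cfg$band[1], cfg$band[2], seg_len)
    purrr::map(space, ~ fit_model(csd, .x, sign = cfg$sign,
                                  n_starts = cfg$n_starts,
                                  seed = cfg$seed + 97L * i + .x))
  })
  report$fits <- fits
  report$per_epoch_bms <- purrr::map(fits, bms)
  le <- purrr::map(fits, ~ vapply(.x, function(f) f$log_evidence, numeric(1)))
  tot <- Reduce(`+`, le)
  agg <- tibble::tibble(
    model_id = as.character(space), log_evidence = tot,
    rel_log_evidence = tot - min(tot),
    posterior = exp(tot - max(tot)) / sum(exp(tot - max(tot)))
  )
  report$bms <- structure(agg,
    class = c("cpg_bms", class(tibble::tibble())),
    winner = as.character(space)[which.max(tot)]
  )
  win <- which.max(tot)
  winner_fits <- purrr::map(fits, ~ .x[[win]])
  report$strengths <- summarize_strengths(winner_fits)
  finish_report(report, cfg)
}

build_simulation <- function(cfg) {
  s <- cfg$simulation
  strengths <- as.list(s$strengths %||% list(intra = 0.3, inter = 0.2, diag = 0.1))
  net <- make_architecture_network(
    s$architecture_id %||% 2, s$n_segments %||% 2, strengths,
    intrinsic_freqs = s$intrinsic_freqs %||% 0.2,
    sign = s$sign %||% "excitatory"
  )
  par_fields <- intersect(names(s), names(formals(simulation_params)))
  params <- do.call(simulation_params,
                    c(s[par_fields], if (!"seed" %in% par_fields) list(seed = cfg$seed)))
  list(network = net, params = params)
}

finish_report <- function(report, cfg) {
  report$provenance <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("cpgnet")),
    config_hash = sum(utf8ToInt(jsonlite::toJSON(cfg[order(names(cfg))],
                                                 auto_unbox = TRUE, force = TRUE)))
  )
  structure(report, class = "cpg_report")
}

#' @exportS3Method base::print
print.cpg_report <- function(x, ...) {
  cat(sprintf("<cpg_report> mode %s, seed %s\n", x$mode, x$provenance$seed))
  if (!is.null(x$pc)) print(x$pc)
  if (!is.null(x$bms)) print(x$bms)
  if (!is.null(x$changes)) print(x$changes)
  invisible(x)
}

#' Write the numeric summaries of a report to JSON
#'
#' Serialises configuration, provenance, per-pair coupling likelihoods,
#' model-selection tables and condition changes (not the bulky raw objects).
#'
#' @param report A `cpg_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- list(
    mode = report$mode,
    config = report$config[setdiff(names(report$config), "simulation")],
    simulation = report$config$simulation,
    provenance = report$provenance,
    pc = report$pc,
    epochs = report$epochs,
    bms = if (!is.null(report$bms)) tibble::as_tibble(report$bms),
    winner = if (!is.null(report$bms)) bms_winner(report$bms),
    strengths = if (!is.null(report$strengths)) tibble::as_tibble(report$strengths),
    changes = report$changes,
    note = "raw p-values; no multiple-comparison correction applied"
  )
  jsonlite::write_json(out[!vapply(out, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
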