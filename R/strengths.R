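#' Summarise coupling strengths across fits with left-right symmetrisation
#'
#' Under the left-right symmetry assumption each directed connection and its
#' mirror image (sides L and R swapped on both endpoints) measure the same
#' anatomical pathway, so their fitted strengths are averaged within each
#' fit. Strengths are then normalised per fit: `"max_to_1"` divides by the
#' maximum symmetrised strength (so the strongest connection reads 1 a.u.);
#' `"reference_connection"` divides by the mean strength of a named
#' connection class (e.g. `"meso-meso"`). Only such normalised comparisons
#' are meaningful: the fitted strengths have no absolute physical scale.
#'
#' @param fits List of `cpg_fit` objects sharing one architecture.
#' @param normalization `"max_to_1"` or `"reference_connection"`.
#' @param reference Connection class used when
#'   `normalization = "reference_connection"`.
#' @return Tibble with one row per symmetrised connection: `connection`,
#'   `class`, `mean`, `sd`, `n`; attributes `per_fit` (long per-fit values)
#'   and `tests` (pairwise class t-tests, when >= 2 fits).
#' @export
summarize_strengths <- function(fits,
                                normalization = c("max_to_1", "reference_connection"),
                                reference = "meso-meso") {
  normalization <- match.arg(normalization)
  if (length(fits) == 0) abort("summarize_strengths needs at least one fit")
  if (inherits(fits, "cpg_fit")) fits <- list(fits)
  ids <- purrr::map_chr(fits, ~ as.character(.x$architecture$id))
  if (length(unique(ids)) != 1) abort("all fits must share one architecture")

  per_fit <- purrr::imap_dfr(fits, function(f, i) {
    ed <- tidy(f)
    if (nrow(ed) == 0) abort("nothing to normalize: architecture has no connections")
    sym <- symmetrize_edges(ed)
    denom <- switch(normalization,
      max_to_1 = max(sym$strength),
      reference_connection = mean(sym$strength[sym$class == reference])
    )
    if (!is.finite(denom) || denom <= 0) {
      abort("nothing to normalize: zero or missing reference strength")
    }
    dplyr::mutate(sym, fit = i, strength = .data$strength / denom)
  })

  out <- per_fit |>
    dplyr::group_by(.data$connection, .data$class) |>
    dplyr::summarise(
      mean = mean(.data$strength), sd = stats::sd(.data$strength),
      n = dplyr::n(), .groups = "drop"
    )
  tests <- NULL
  if (length(fits) >= 2) {
    class_vals <- per_fit |>
      dplyr::group_by(.data$fit, .data$class) |>
      dplyr::summarise(value = mean(.data$strength), .groups = "drop") |>
      dplyr::select("class", "value")
    tests <- compare_connection_classes(class_vals)
  }
  structure(out, per_fit = per_fit, tests = tests)
}

# average each directed edge with its left-right mirror image
symmetrize_edges <- function(edges) {
  mirror <- function(lbl) {
    info <- channel_info(lbl)
    paste(info$segment, ifelse(info$side == "L", "R", "L"), sep = "_")
  }
  id <- paste(edges$from, edges$to, sep = ">")
  mid <- paste(mirror(edges$from), mirror(edges$to), sep = ">")
  key <- pmin(id, mid)
  edges |>
    dplyr::mutate(key = key, strength = abs(.data$strength)) |>
    dplyr::group_by(.data$key, .data$class) |>
    dplyr::summarise(strength = mean(.data$strength), .groups = "drop") |>
    dplyr::transmute(
      connection = sub(">", " > ", .data$key, fixed = TRUE),
      class = .data$class, strength = .data$strength
    )
}
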