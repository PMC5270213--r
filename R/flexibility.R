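#' Classify SM functions by the functional makeup of their PM homologs
#'
#' For every SM grouping key with at least one homolog hit, compares each PM
#' hit's key to the SM key at the map's level and assigns one of three
#' categories: `ALL_SAME` — every homolog shares the key (a monofunctional
#' family), `MIXED` — some do (a multifunctional family), `ALL_DIFF` — none
#' does (the function most likely changed after recruitment).
#'
#' @param map a `function_hit_map` from [function_hit_map()].
#' @return tibble of class `flex_classification`: `key`, `n_hits`, `n_same`,
#'   `category` (factor ALL_SAME/MIXED/ALL_DIFF); attribute `level`.
#' @export
classify_functions <- function(map) {
  stopifnot(inherits(map, "function_hit_map"))
  out <- tibble::as_tibble(map) |>
    dplyr::group_by(key = .data$sm_key) |>
    dplyr::summarise(
      n_hits = dplyr::n(),
      n_same = sum(.data$same),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      category = factor(
        dplyr::case_when(
          .data$n_same == .data$n_hits ~ "ALL_SAME",
          .data$n_same == 0 ~ "ALL_DIFF",
          TRUE ~ "MIXED"
        ),
        levels = c("ALL_SAME", "MIXED", "ALL_DIFF")
      )
    ) |>
    dplyr::arrange(.data$key)
  structure(out,
    class = c("flex_classification", class(tibble::tibble())),
    level = map_level(map)
  )
}

#' Summarize a functional-flexibility classification
#'
#' Counts keys per category and expresses them as percent fractions. By
#' default the denominator is the number of classified keys (those with at
#' least one homolog), in which case the fractions sum to 100. Passing
#' `n_total` uses a larger universe as denominator — e.g. all SM subdivisions
#' including those without any homolog — reproducing summary percentages
#' quoted against the full function inventory.
#'
#' @param classifications a `flex_classification`.
#' @param n_total optional denominator overriding the classified-key count.
#' @return tibble of class `flex_summary`: `category`, `n`, `fraction`
#'   (percent); attributes `n_keys` (classified), `n_total` (denominator),
#'   `level`.
#' @export
summarize_classification <- function(classifications, n_total = NULL) {
  stopifnot(inherits(classifications, "flex_classification"))
  if (nrow(classifications) == 0) {
    stop("no classifications to summarize", call. = FALSE)
  }
  n_keys <- nrow(classifications)
  denom <- if (is.null(n_total)) n_keys else n_total
  stopifnot(denom >= n_keys)
  out <- tibble::as_tibble(classifications) |>
    dplyr::count(.data$category, name = "n", .drop = FALSE) |>
    dplyr::mutate(fraction = 100 * .data$n / denom)
  structure(out,
    class = c("flex_summary", class(tibble::tibble())),
    n_keys = n_keys,
    n_total = denom,
    level = attr(classifications, "level")
  )
}

#' Rate of functional conservation per group
#'
#' For each grouping key `g` at the map's level, the hit-weighted fraction
#' `fc(g)` of PM homolog hits to SM queries in `g` whose PM key equals `g`:
#' `fc = 1` means every homolog of that group's SM enzymes keeps the
#' function, `fc = 0` that all homologs catalyze something else. Groups
#' without hits are omitted.
#'
#' @param map a `function_hit_map`.
#' @return tibble of class `fc_table`: `key`, `n_hits`, `n_same`, `fc`;
#'   attribute `level`.
#' @export
functional_conservation <- function(map) {
  stopifnot(inherits(map, "function_hit_map"))
  out <- tibble::as_tibble(map) |>
    dplyr::group_by(key = .data$sm_key) |>
    dplyr::summarise(
      n_hits = dplyr::n(),
      n_same = sum(.data$same),
      .groups = "drop"
    ) |>
    dplyr::mutate(fc = .data$n_same / .data$n_hits) |>
    dplyr::arrange(.data$key)
  structure(out,
    class = c("fc_table", class(tibble::tibble())),
    level = map_level(map)
  )
}

#' Fraction of SM functions recruited from PM
#'
#' Percentage of the SM function inventory for which a PM homolog exists —
#' the lower bound on how much of the secondary-metabolism enzyme repertoire
#' traces back to primary metabolism.
#'
#' @param n_shared number of SM functions with at least one PM homolog.
#' @param n_total_sm total number of SM functions.
#' @return scalar percent, `100 * n_shared / n_total_sm`.
#' @export
recruitment_fraction <- function(n_shared, n_total_sm) {
  stopifnot(n_total_sm > 0, n_shared >= 0, n_shared <= n_total_sm)
  100 * n_shared / n_total_sm
}

#' Recruitment summary of an SM function inventory
#'
#' @inheritParams recruitment_fraction
#' @return one-row tibble: `n_shared`, `n_total_sm`, `n_exclusive`
#'   (functions with no PM homolog), `recruited_percent`.
#' @export
recruitment_summary <- function(n_shared, n_total_sm) {
  tibble::tibble(
    n_shared = n_shared,
    n_total_sm = n_total_sm,
    n_exclusive = n_total_sm - n_shared,
    recruited_percent = recruitment_fraction(n_shared, n_total_sm)
  )
}

#' The "EC hits-counts" table of a function hit map
#'
#' Per SM key: total kept homolog hits (`TOT`), hits with the same key
#' (`SAME`) and with a different key (`DIFF`) at the map's level.
#'
#' @param map a `function_hit_map`.
#' @return tibble `key`, `TOT`, `SAME`, `DIFF`.
#' @export
ec_hits_counts <- function(map) {
  stopifnot(inherits(map, "function_hit_map"))
  tibble::as_tibble(map) |>
    dplyr::group_by(key = .data$sm_key) |>
    dplyr::summarise(
      TOT = dplyr::n(),
      SAME = sum(.data$same),
      DIFF = sum(!.data$same),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$key)
}
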