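#' Normalized EC-frequency spectrum of a catalog
#'
#' Counts enzyme records per grouping key at the requested EC level and
#' normalizes to percent. Each record complete at the level contributes
#' exactly one count; records whose EC is wildcarded above the level are
#' dropped from that level's denominator (their number is recorded in the
#' `n_dropped` attribute). Frequencies are record-based — an EC carried by
#' many enzymes weighs accordingly — with `weighting = "distinct_ec"`
#' available as a sensitivity alternative that counts each distinct EC once.
#'
#' @param catalog a filtered `enzyme_catalog` (one EC per record).
#' @param level one of [ec_levels()].
#' @param weighting `"record"` (default) or `"distinct_ec"`.
#' @return tibble of class `ec_freq` with columns `key`, `n`, `freq`
#'   (percent; sums to 100 on non-empty tables), sorted by key; attributes
#'   `level`, `n_records_used`, `n_dropped`, `role`.
#' @export
ec_frequencies <- function(catalog, level = "class",
                           weighting = c("record", "distinct_ec")) {
  weighting <- match.arg(weighting)
  level <- match.arg(level, ec_levels())
  stopifnot(inherits(catalog, "enzyme_catalog"))
  keys <- if (nrow(catalog) > 0) ec_key(catalog$ec, level) else character()
  used <- keys[!is.na(keys)]
  if (weighting == "distinct_ec") {
    ecs <- catalog$ec[!is.na(keys)]
    used <- ec_key(unique(ecs), level)
  }
  tab <- tibble::tibble(key = used) |>
    dplyr::count(.data$key, name = "n") |>
    dplyr::mutate(freq = 100 * .data$n / sum(.data$n)) |>
    dplyr::arrange(.data$key)
  structure(tab,
    class = c("ec_freq", class(tibble::tibble())),
    level = level,
    n_records_used = length(used),
    n_dropped = sum(is.na(keys)),
    role = attr(catalog, "role")
  )
}

freq_level <- function(x) attr(x, "level")

#' Overrepresentation of EC keys in the SM spectrum
#'
#' For every grouping key present in either spectrum, the ratio
#' `overrep = f_SM / f_PM` of its normalized frequencies. Keys absent from
#' the PM spectrum but present in SM have no finite ratio and are flagged
#' `absent_in_pm`; keys absent from SM get ratio 0.
#'
#' @param sm_freq,pm_freq `ec_freq` tables at the same level (SM and PM side).
#' @param flag_threshold keys with ratio above this are marked in the
#'   `flagged` column (default 20, the highlighting threshold used for rare
#'   strongly SM-biased subdivisions).
#' @return tibble of class `overrep_tbl`: `key`, `f_sm`, `f_pm`, `ratio`,
#'   `absent_in_pm`, `flagged`; attribute `level`.
#' @export
overrep_ratios <- function(sm_freq, pm_freq, flag_threshold = 20) {
  if (!identical(freq_level(sm_freq), freq_level(pm_freq))) {
    stop("frequency tables are at different levels", call. = FALSE)
  }
  joined <- dplyr::full_join(
    tibble::as_tibble(sm_freq)[c("key", "freq")] |> dplyr::rename(f_sm = "freq"),
    tibble::as_tibble(pm_freq)[c("key", "freq")] |> dplyr::rename(f_pm = "freq"),
    by = "key"
  ) |>
    dplyr::mutate(
      f_sm = dplyr::coalesce(.data$f_sm, 0),
      f_pm = dplyr::coalesce(.data$f_pm, 0),
      absent_in_pm = .data$f_pm == 0 & .data$f_sm > 0,
      ratio = dplyr::case_when(
        .data$f_sm == 0 ~ 0,
        .data$f_pm > 0 ~ .data$f_sm / .data$f_pm,
        TRUE ~ NA_real_
      ),
      flagged = !is.na(.data$ratio) & .data$ratio > flag_threshold
    ) |>
    dplyr::arrange(.data$key)
  structure(joined,
    class = c("overrep_tbl", class(tibble::tibble())),
    level = freq_level(sm_freq),
    flag_threshold = flag_threshold
  )
}

#' Shared and exclusive enzyme functions of two catalogs
#'
#' Partitions the union of grouping keys present in the SM and PM catalogs
#' into functions occurring on both sides, only in SM, and only in PM.
#'
#' @param sm_catalog,pm_catalog filtered `enzyme_catalog`s.
#' @param level one of [ec_levels()].
#' @return list with character-vector elements `shared`, `sm_only`,
#'   `pm_only` (sorted, disjoint, jointly covering the key union).
#' @export
shared_exclusive_functions <- function(sm_catalog, pm_catalog, level = "full") {
  level <- match.arg(level, ec_levels())
  keyset <- function(cat) {
    k <- ec_key(cat$ec, level)
    sort(unique(k[!is.na(k)]), method = "radix")
  }
  sm <- keyset(sm_catalog)
  pm <- keyset(pm_catalog)
  list(
    shared = intersect(sm, pm),
    sm_only = setdiff(sm, pm),
    pm_only = setdiff(pm, sm)
  )
}

#' Squared Pearson correlation of two frequency spectra
#'
#' Pairs the two tables' frequencies by grouping key and returns the squared
#' Pearson correlation coefficient. Under `pairing = "union_zero_fill"`
#' (default) keys missing from one table contribute frequency 0; under
#' `"intersection"` only keys present in both tables are paired. Fewer than
#' three pairs, or zero variance on either side, is an error.
#'
#' @param a,b `ec_freq` tables at the same level.
#' @param pairing `"union_zero_fill"` or `"intersection"`.
#' @return scalar r-squared in \[0, 1\].
#' @export
frequency_correlation <- function(a, b,
                                  pairing = c("union_zero_fill", "intersection")) {
  pairing <- match.arg(pairing)
  if (!identical(freq_level(a), freq_level(b))) {
    stop("frequency tables are at different levels", call. = FALSE)
  }
  join <- if (pairing == "union_zero_fill") dplyr::full_join else dplyr::inner_join
  paired <- join(
    tibble::as_tibble(a)[c("key", "freq")] |> dplyr::rename(fa = "freq"),
    tibble::as_tibble(b)[c("key", "freq")] |> dplyr::rename(fb = "freq"),
    by = "key"
  ) |>
    dplyr::mutate(
      fa = dplyr::coalesce(.data$fa, 0),
      fb = dplyr::coalesce(.data$fb, 0)
    )
  if (nrow(paired) < 3) {
    stop("fewer than 3 key pairs; correlation undefined", call. = FALSE)
  }
  if (stats::sd(paired$fa) == 0 || stats::sd(paired$fb) == 0) {
    stop("zero variance in paired frequencies; correlation undefined",
      call. = FALSE
    )
  }
  stats::cor(paired$fa, paired$fb)^2
}

#' Write a frequency or overrepresentation table as TSV
#'
#' Tables are written sorted by key with full-precision values; rounding is a
#' display concern left to the reader.
#'
#' @param x an `ec_freq` or `overrep_tbl`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
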