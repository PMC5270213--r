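#' Read a homology hit table (BLAST tabular dialect)
#'
#' Parses the standard 12-column tab-separated hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score), optionally extended with `qlen`
#' and `slen` columns. Malformed rows are rejected with their line numbers.
#'
#' @param path path to the tab-separated hit table; `#` comment lines are
#'   ignored.
#' @param dialect `"std12"` (12 columns) or `"std12_lens"` (14 columns with
#'   trailing query/subject sequence lengths).
#' @return tibble with columns `query_id`, `subject_id`, `pident`, `aln_len`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore` (and `qlen`, `slen` for the extended dialect).
#' @export
read_hit_table <- function(path, dialect = c("std12", "std12_lens")) {
  dialect <- match.arg(dialect)
  n_cols <- if (dialect == "std12") 12L else 14L
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) != n_cols
  if (any(bad)) {
    stop(
      "hit table line(s) with wrong column count (expected ", n_cols, "): ",
      paste(utils::head(line_no[bad], 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (length(fields) == 0) {
    mat <- matrix(character(), ncol = n_cols)
  } else {
    mat <- matrix(unlist(fields), ncol = n_cols, byrow = TRUE)
  }
  cols <- c(
    "query_id", "subject_id", "pident", "aln_len", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  if (dialect == "std12_lens") cols <- c(cols, "qlen", "slen")
  colnames(mat) <- cols
  out <- tibble::as_tibble(mat)
  num_cols <- setdiff(cols, c("query_id", "subject_id"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    if (anyNA(v) && any(!is.na(out[[cn]]))) {
      bad_ln <- line_no[is.na(v)]
      stop("non-numeric '", cn, "' in hit table at line(s): ",
        paste(utils::head(bad_ln, 5), collapse = ", "),
        call. = FALSE
      )
    }
    out[[cn]] <- v
  }
  if (nrow(out) > 0 && any(out$evalue < 0)) {
    stop("negative E-value in hit table", call. = FALSE)
  }
  out
}

#' Filter homology hits by E-value and length criteria
#'
#' Applies the homolog-acceptance rules: a hit is kept iff its E-value is at
#' or below the cutoff (default 1e-20; 1e-10 is the usual relaxed control)
#' and the subject's protein length differs from the *query's* length by at
#' most `length_tolerance` (default 30 percent, boundary inclusive) — the
#' length rule guards against multi-domain false positives sharing only one
#' domain. Self-hits (identical gene ids) are removed by default. Duplicate
#' (query, subject) rows, as produced by multi-HSP alignments, are collapsed
#' to the minimum-E-value row before filtering, so each homolog pair counts
#' once.
#'
#' Lengths come from `qlen`/`slen` columns when present, otherwise from the
#' supplied catalogs.
#'
#' @param hits tibble from [read_hit_table()].
#' @param query_catalog,subject_catalog `enzyme_catalog`s used to resolve
#'   protein lengths (may be `NULL` when the hit table carries
#'   `qlen`/`slen`).
#' @param evalue_cutoff keep hits with `evalue <= evalue_cutoff`.
#' @param length_tolerance maximal `|L_subject - L_query| / L_query`.
#' @param remove_self_hits drop rows with `query_id == subject_id`.
#' @return the kept hits, sorted by (query, subject); attribute `rejections`
#'   is a tibble (`query_id`, `subject_id`, `reason`) naming every removed
#'   pair, retrievable with [hit_rejections()].
#' @export
filter_hits <- function(hits, query_catalog = NULL, subject_catalog = NULL,
                        evalue_cutoff = 1e-20, length_tolerance = 0.30,
                        remove_self_hits = TRUE) {
  stopifnot(evalue_cutoff > 0, length_tolerance >= 0, length_tolerance < 1)
  # collapse multi-HSP rows: best (lowest) E-value, ties by highest bitscore
  hits <- hits |>
    dplyr::arrange(
      .data$query_id, .data$subject_id, .data$evalue,
      dplyr::desc(.data$bitscore)
    ) |>
    dplyr::distinct(.data$query_id, .data$subject_id, .keep_all = TRUE)

  qlen <- resolve_lengths(hits, "qlen", hits$query_id, query_catalog, "query")
  slen <- resolve_lengths(hits, "slen", hits$subject_id, subject_catalog, "subject")

  reason <- rep(NA_character_, nrow(hits))
  if (remove_self_hits) {
    reason[is.na(reason) & hits$query_id == hits$subject_id] <- "self_hit"
  }
  reason[is.na(reason) & hits$evalue > evalue_cutoff] <- "evalue"
  reason[is.na(reason) & abs(slen - qlen) / qlen > length_tolerance] <- "length"

  kept <- hits[is.na(reason), , drop = FALSE]
  rejections <- tibble::tibble(
    query_id = hits$query_id[!is.na(reason)],
    subject_id = hits$subject_id[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  structure(kept,
    class = class(tibble::tibble()),
    rejections = rejections,
    filter_config = list(
      evalue_cutoff = evalue_cutoff,
      length_tolerance = length_tolerance,
      remove_self_hits = remove_self_hits
    )
  )
}

resolve_lengths <- function(hits, col, ids, catalog, side) {
  if (col %in% names(hits)) {
    return(hits[[col]])
  }
  if (is.null(catalog)) {
    stop("hit table lacks ", col, " and no ", side,
      " catalog was supplied to resolve lengths",
      call. = FALSE
    )
  }
  idx <- match(ids, catalog$gene_id)
  if (anyNA(idx) && length(ids) > 0) {
    stop(
      "unresolvable ", side, " id(s) in hit table: ",
      paste(utils::head(unique(ids[is.na(idx)]), 5), collapse = ", "),
      call. = FALSE
    )
  }
  catalog$length[idx]
}

#' Per-hit rejection log of [filter_hits()]
#' @param hits a filtered hit tibble.
#' @return tibble (`query_id`, `subject_id`, `reason`), reason one of
#'   `self_hit`, `evalue`, `length`.
#' @export
hit_rejections <- function(hits) attr(hits, "rejections")

#' Map SM functions to the functions of their PM homologs
#'
#' Joins filtered hits with the query (SM) and subject (PM) catalogs and
#' derives, at the requested EC level, one row per kept hit carrying the
#' query's grouping key (`sm_key`) and the subject's (`pm_key`) together with
#' the hit E-value. All hits of all query records bearing the same SM
#' function pool into that function's entry. Hits whose query or subject is
#' incomplete at the level are omitted from that level's view, and hits
#' whose endpoints are absent from the filtered catalogs (no single EC
#' annotation) are dropped (their number is kept in the `n_unannotated`
#' attribute).
#'
#' @param hits filtered hit tibble from [filter_hits()].
#' @param query_catalog,subject_catalog filtered `enzyme_catalog`s (one EC
#'   per record); queries are the SM side, subjects the PM side.
#' @param level one of [ec_levels()].
#' @return tibble of class `function_hit_map` with columns `sm_key`,
#'   `pm_key`, `evalue`, `query_id`, `subject_id`, `same` (keys equal at
#'   level); attribute `level`.
#' @export
function_hit_map <- function(hits, query_catalog, subject_catalog,
                             level = "full") {
  level <- match.arg(level, ec_levels())
  q_idx <- match(hits$query_id, query_catalog$gene_id)
  s_idx <- match(hits$subject_id, subject_catalog$gene_id)
  annotated <- !is.na(q_idx) & !is.na(s_idx)
  hits <- hits[annotated, , drop = FALSE]
  q_idx <- q_idx[annotated]
  s_idx <- s_idx[annotated]
  map <- tibble::tibble(
    sm_key = ec_key(query_catalog$ec[q_idx], level),
    pm_key = ec_key(subject_catalog$ec[s_idx], level),
    evalue = hits$evalue,
    query_id = hits$query_id,
    subject_id = hits$subject_id
  ) |>
    dplyr::filter(!is.na(.data$sm_key), !is.na(.data$pm_key)) |>
    dplyr::mutate(same = .data$sm_key == .data$pm_key) |>
    dplyr::arrange(.data$sm_key, .data$pm_key, .data$query_id, .data$subject_id)
  structure(map,
    class = c("function_hit_map", class(tibble::tibble())),
    level = level,
    n_unannotated = sum(!annotated),
    filter_config = attr(hits, "filter_config")
  )
}

map_level <- function(map) attr(map, "level")
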