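#' Enzyme catalogs
#'
#' An enzyme catalog is a role-tagged table of enzyme records: one side holds
#' the primary-metabolism (PM) reference built from BGC-free genomes, the
#' other the secondary-metabolism (SM) set built from biosynthetic gene
#' clusters (BGCs). Collections are the genomes (PM side) or BGCs (SM side)
#' the records come from.
#'
#' Required columns: `gene_id` (unique), `collection_id`, `species_tax`,
#' `ec` (possibly several EC numbers separated by `;`, possibly empty),
#' `length` (protein length in amino acids, > 0), `product` (free text).
#'
#' @param x data frame with the columns above.
#' @param role `"pm"` or `"sm"`.
#' @return A tibble of class `enzyme_catalog` with attributes `role` and,
#'   after [apply_inclusion_filters()], `filter_log`.
#' @export
as_enzyme_catalog <- function(x, role = c("pm", "sm")) {
  role <- match.arg(role)
  required <- c("gene_id", "collection_id", "species_tax", "ec", "length", "product")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(x)[required]
  out$gene_id <- as.character(out$gene_id)
  out$collection_id <- as.character(out$collection_id)
  out$species_tax <- as.character(out$species_tax)
  out$ec <- dplyr::coalesce(as.character(out$ec), "")
  len <- suppressWarnings(as.numeric(out$length))
  if (anyNA(len)) {
    stop("unparseable protein length for gene(s): ",
      paste(utils::head(out$gene_id[is.na(len)], 5), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(len <= 0)) {
    stop("protein length must be > 0 for gene(s): ",
      paste(utils::head(out$gene_id[len <= 0], 5), collapse = ", "),
      call. = FALSE
    )
  }
  out$length <- len
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id in catalog: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  structure(out,
    class = c("enzyme_catalog", class(tibble::tibble())),
    role = role
  )
}

#' Read an enzyme catalog from a tab-separated file
#'
#' The file must be UTF-8 TSV with a header naming the columns documented in
#' [as_enzyme_catalog()]; lines starting with `#` are ignored. An optional
#' companion FASTA of protein sequences can be supplied for a length
#' consistency check (sequence ids must match `gene_id`); the sequences are
#' not otherwise used.
#'
#' @param path path to the catalog TSV.
#' @inheritParams as_enzyme_catalog
#' @param fasta optional path to a protein FASTA whose sequence lengths are
#'   checked against the `length` column.
#' @return an `enzyme_catalog` tibble.
#' @export
read_catalog <- function(path, role = c("pm", "sm"), fasta = NULL) {
  role <- match.arg(role)
  df <- readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  cat <- as_enzyme_catalog(df, role = role)
  if (!is.null(fasta)) {
    seqs <- read_fasta_lengths(fasta)
    common <- intersect(names(seqs), cat$gene_id)
    mism <- common[seqs[common] != cat$length[match(common, cat$gene_id)]]
    if (length(mism) > 0) {
      stop("FASTA sequence length disagrees with catalog for: ",
        paste(utils::head(mism, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  cat
}

read_fasta_lengths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  lens <- tapply(nchar(gsub("\\s", "", lines[!hdr])), grp[!hdr], sum)
  stats::setNames(as.integer(lens), ids)
}

#' Role of a catalog
#' @param x an `enzyme_catalog`.
#' @return `"pm"` or `"sm"`.
#' @export
catalog_role <- function(x) attr(x, "role")

#' Apply the inclusion filters to a catalog
#'
#' Keeps only records annotated with exactly one EC number: records without an
#' EC are removed, and records carrying more than one EC (ambiguous function)
#' are removed as well. The returned catalog's `ec` column holds the single
#' canonical EC per record (wildcarded suffixes such as `1.-.-.-` are kept;
#' the spectrum statistics exclude them per level as needed). The audit trail
#' is attached as attribute `filter_log` and retrievable with [filter_log()].
#'
#' @param catalog an `enzyme_catalog`.
#' @inheritParams parse_ec
#' @return the filtered `enzyme_catalog`.
#' @export
apply_inclusion_filters <- function(catalog, max_class = 6,
                                    allow_preliminary = FALSE) {
  stopifnot(inherits(catalog, "enzyme_catalog"))
  ec_split <- strsplit(catalog$ec, ";", fixed = TRUE)
  ec_split <- lapply(ec_split, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
  n_ec <- lengths(ec_split)
  keep <- n_ec == 1L
  out <- catalog[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    out$ec <- ec_canonical(vapply(ec_split[keep], identity, character(1)),
      max_class = max_class, allow_preliminary = allow_preliminary
    )
  }
  log <- tibble::tibble(
    n_input = nrow(catalog),
    n_removed_no_ec = sum(n_ec == 0L),
    n_removed_multi_ec = sum(n_ec > 1L),
    n_kept = nrow(out)
  )
  structure(out,
    class = class(catalog),
    role = attr(catalog, "role"),
    filter_log = log
  )
}

#' Retrieve the inclusion-filter audit log
#' @param catalog a filtered `enzyme_catalog`.
#' @return one-row tibble: `n_input`, `n_removed_no_ec`, `n_removed_multi_ec`,
#'   `n_kept` (which always sum up: input = removed + kept).
#' @export
filter_log <- function(catalog) attr(catalog, "filter_log")

#' Leave-one-collection-out split
#'
#' Splits a catalog into the records of one held-out collection (the queries)
#' and all remaining records (the references). This is the control used to
#' baseline functional diversity: each genome against the rest of the PM set,
#' or each BGC against the rest of the SM set.
#'
#' @param catalog an `enzyme_catalog`.
#' @param held_out a `collection_id` present in the catalog.
#' @return list with elements `queries` and `references`, both
#'   `enzyme_catalog` tibbles; they partition the input records. A catalog
#'   with a single collection yields an empty reference with a warning.
#' @export
leave_one_out <- function(catalog, held_out) {
  stopifnot(inherits(catalog, "enzyme_catalog"))
  collections <- unique(catalog$collection_id)
  if (!held_out %in% collections) {
    stop("unknown collection_id: ", held_out, call. = FALSE)
  }
  if (length(collections) < 2L) {
    warning("catalog has a single collection; reference set is empty",
      call. = FALSE
    )
  }
  is_q <- catalog$collection_id == held_out
  rebuild <- function(df) {
    structure(df,
      class = class(catalog), role = attr(catalog, "role"),
      filter_log = attr(catalog, "filter_log")
    )
  }
  list(
    queries = rebuild(catalog[is_q, , drop = FALSE]),
    references = rebuild(catalog[!is_q, , drop = FALSE])
  )
}

#' @export
print.enzyme_catalog <- function(x, ...) {
  cat(
    "# enzyme_catalog (", toupper(catalog_role(x)), " side): ",
    nrow(x), " records in ", length(unique(x$collection_id)),
    " collection(s)\n",
    sep = ""
  )
  NextMethod()
}
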