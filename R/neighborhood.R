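#' Read a genome gene-order table
#'
#' One row per gene in genomic order. Columns: `replicon_id`, `ordinal`
#' (integer gene-order position, unique within replicon), `gene_id`,
#' `strand` (`+`/`-`), `product`, `ec` (possibly empty or `;`-separated),
#' `pathways` (`;`-separated pathway ids, possibly empty).
#'
#' @param path TSV file; `#` comment lines ignored.
#' @return tibble with the columns above plus `pathway_ids`, a list column
#'   of pathway id vectors.
#' @export
read_genome_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  # pad rows whose trailing ec/pathways fields are omitted
  n_fields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  width <- n_fields[1]
  short <- n_fields < width
  lines[short] <- paste0(
    lines[short],
    strrep("\t", width - n_fields[short])
  )
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  as_genome_table(df)
}

#' @rdname read_genome_table
#' @param x data frame with the documented columns.
#' @export
as_genome_table <- function(x) {
  required <- c("replicon_id", "ordinal", "gene_id", "strand", "product", "ec", "pathways")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("genome table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(x)[required]
  out$ordinal <- as.integer(out$ordinal)
  out$ec <- dplyr::coalesce(as.character(out$ec), "")
  out$pathways <- dplyr::coalesce(as.character(out$pathways), "")
  if (anyNA(out$ordinal)) stop("unparseable ordinal in genome table", call. = FALSE)
  dup <- duplicated(out[c("replicon_id", "ordinal")])
  if (any(dup)) stop("duplicate (replicon_id, ordinal) in genome table", call. = FALSE)
  out$pathway_ids <- lapply(strsplit(out$pathways, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
  dplyr::arrange(out, .data$replicon_id, .data$ordinal)
}

#' Read a pathway id/name map
#'
#' @param path TSV with columns `pathway_id`, `pathway_name`.
#' @return tibble with those columns.
#' @export
read_pathway_map <- function(path) {
  readr::read_tsv(path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )[c("pathway_id", "pathway_name")]
}

#' Extract the gene neighborhood around an anchor
#'
#' Returns the genes whose gene-order position lies within `k` of the anchor
#' on the anchor's replicon — the window used as an operon proxy (bacterial
#' operons are typically three to four genes, nearly all shorter than ten).
#' Windowing is by gene order, not base-pair distance; strand is carried but
#' ignored. Linear replicons truncate at their ends; `circular = TRUE` wraps
#' around.
#'
#' @param genome a genome table from [read_genome_table()].
#' @param anchor_id `gene_id` of the putative PM homolog at the window
#'   center.
#' @param k window half-width in genes (default 10).
#' @param circular wrap around the replicon ends.
#' @return tibble of class `gene_neighborhood`: the window's gene rows plus
#'   an `offset` column (gene-order distance to the anchor, anchor = 0);
#'   attributes `anchor`, `k`, `circular`.
#' @export
extract_neighborhood <- function(genome, anchor_id, k = 10, circular = FALSE) {
  stopifnot(k >= 1)
  if (!"pathway_ids" %in% names(genome)) genome <- as_genome_table(genome)
  hit <- which(genome$gene_id == anchor_id)
  if (length(hit) == 0) stop("anchor gene not found: ", anchor_id, call. = FALSE)
  if (length(hit) > 1) stop("ambiguous anchor gene id: ", anchor_id, call. = FALSE)
  repl <- genome$replicon_id[hit]
  on_repl <- genome[genome$replicon_id == repl, , drop = FALSE]
  on_repl <- on_repl[order(on_repl$ordinal), , drop = FALSE]
  pos <- which(on_repl$gene_id == anchor_id)
  n <- nrow(on_repl)
  if (circular && n > 2 * k) {
    idx <- ((pos - k - 1):(pos + k - 1)) %% n + 1
    offsets <- -k:k
  } else if (circular) {
    idx <- seq_len(n) # window covers the whole replicon
    offsets <- seq_len(n) - pos
  } else {
    idx <- max(1, pos - k):min(n, pos + k)
    offsets <- idx - pos
  }
  out <- on_repl[idx, , drop = FALSE]
  out$offset <- offsets
  structure(out,
    class = c("gene_neighborhood", class(tibble::tibble())),
    anchor = anchor_id, k = k, circular = circular
  )
}

#' Label neighborhood genes as possible PM or SM contributors
#'
#' `P` marks a possible contribution to primary metabolism: the gene carries
#' a fully specified EC number that occurs in the PM reference set. `S`
#' marks a possible contribution to secondary metabolism: the gene is mapped
#' to the species' secondary-metabolite biosynthesis pathway
#' (`sm_pathway_id`), or — when an EC-based SM key set is supplied instead —
#' its canonical EC (wildcards included) is a member of `sm_keys`. Genes
#' without any EC annotation get no `P`.
#'
#' @param nh a `gene_neighborhood`.
#' @param pm_keys character vector of full EC keys present on the PM side.
#' @param sm_keys optional character vector of canonical EC strings mapped
#'   to secondary-metabolite biosynthesis.
#' @param sm_pathway_id optional pathway id whose members get `S` (e.g. the
#'   species' "Biosynthesis of secondary metabolites" map).
#' @return the neighborhood with logical columns `label_P`, `label_S`.
#' @export
assign_labels <- function(nh, pm_keys, sm_keys = NULL, sm_pathway_id = NULL) {
  stopifnot(inherits(nh, "gene_neighborhood"))
  gene_ecs <- lapply(strsplit(nh$ec, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v <- v[nzchar(v)]
    if (length(v) == 0) character() else ec_canonical(v)
  })
  nh$label_P <- vapply(gene_ecs, function(e) {
    if (length(e) == 0) {
      return(FALSE)
    }
    complete <- e[ec_complete_at(e, "full")]
    any(complete %in% pm_keys)
  }, logical(1))
  s_by_ec <- if (is.null(sm_keys)) {
    rep(FALSE, nrow(nh))
  } else {
    vapply(gene_ecs, function(e) any(e %in% sm_keys), logical(1))
  }
  s_by_pathway <- if (is.null(sm_pathway_id)) {
    rep(FALSE, nrow(nh))
  } else {
    vapply(nh$pathway_ids, function(p) any(sm_pathway_id %in% p), logical(1))
  }
  nh$label_S <- s_by_ec | s_by_pathway
  nh
}

#' Count P and S labels in a neighborhood
#'
#' @param nh a labeled `gene_neighborhood` (anchor included in the counts).
#' @return one-row tibble `n_P`, `n_S`.
#' @export
summarize_labels <- function(nh) {
  stopifnot(inherits(nh, "gene_neighborhood"))
  if (is.null(nh$label_P)) stop("neighborhood is not labeled", call. = FALSE)
  tibble::tibble(n_P = sum(nh$label_P), n_S = sum(nh$label_S))
}

#' Summarize pathway membership in the outer and inner windows
#'
#' For each pathway attached to at least one gene of the neighborhood (built
#' with half-width `k_outer`), counts the member genes in the full window
#' (`n_outer`) and within `k_inner` genes of the anchor (`n_inner`, anchor
#' included). Rows are sorted by decreasing `n_outer`, then pathway id — the
#' `n/m pathway` lines of the per-cluster reports.
#'
#' @param nh a `gene_neighborhood` extracted with `k = k_outer`.
#' @param k_inner inner window half-width (default 2).
#' @param pathway_map optional tibble (`pathway_id`, `pathway_name`) to
#'   attach display names.
#' @return tibble `n_outer`, `n_inner`, `pathway_id`, `pathway_name`.
#' @export
summarize_pathways <- function(nh, k_inner = 2, pathway_map = NULL) {
  stopifnot(inherits(nh, "gene_neighborhood"))
  k_outer <- attr(nh, "k")
  stopifnot(k_inner >= 1, k_inner <= k_outer)
  long <- tibble::tibble(
    offset = rep(nh$offset, lengths(nh$pathway_ids)),
    pathway_id = unlist(nh$pathway_ids, use.names = FALSE) %||% character()
  )
  out <- long |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      n_outer = dplyr::n(),
      n_inner = sum(abs(.data$offset) <= k_inner),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_outer), .data$pathway_id)
  if (!is.null(pathway_map)) {
    out <- dplyr::left_join(out, pathway_map, by = "pathway_id")
  } else {
    out$pathway_name <- NA_character_
  }
  out[c("n_outer", "n_inner", "pathway_id", "pathway_name")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
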