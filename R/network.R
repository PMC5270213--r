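#' E-value binning scheme for change-graph edges
#'
#' Bins span the whole positive E-value axis: edges list the upper bounds of
#' successive bins in decreasing magnitude; values above the first edge fall
#' in an open top bin. With the defaults, a mean E-value of 1e-30 is labelled
#' `(1e-50,1e-20]` and 1e-120 is `<=1e-100`.
#'
#' @param edges strictly decreasing positive E-value upper bounds.
#' @return object of class `evalue_binning`.
#' @export
evalue_binning <- function(edges = c(1e-20, 1e-50, 1e-100)) {
  stopifnot(length(edges) >= 1, all(edges > 0), all(diff(edges) < 0))
  n <- length(edges)
  fmt <- vapply(edges, format, character(1), trim = TRUE)
  inner <- if (n > 1) sprintf("(%s,%s]", fmt[-1], fmt[-n]) else character()
  labels <- c(paste0(">", fmt[1]), inner, paste0("<=", fmt[n]))
  structure(list(edges = edges, labels = labels), class = "evalue_binning")
}

#' Assign E-values to bins
#'
#' @param evalue numeric vector of positive E-values.
#' @param binning an [evalue_binning()].
#' @return character vector of bin labels; every positive value falls in
#'   exactly one bin.
#' @export
bin_evalue <- function(evalue, binning = evalue_binning()) {
  stopifnot(inherits(binning, "evalue_binning"), all(evalue > 0))
  breaks <- c(Inf, binning$edges, 0)
  idx <- findInterval(-evalue, -breaks, left.open = FALSE)
  binning$labels[idx]
}

#' Build the directed PM-to-SM functional-change graph
#'
#' Nodes are grouping keys at the map's level, annotated with their homolog
#' hit count, rate of functional conservation `fc`, and whether the key is
#' present in the PM catalog at all (keys absent from PM are the network's
#' `-`-marked nodes). Every homolog hit whose PM key `p` differs from its SM
#' key `s` contributes to a directed edge `p -> s` signalling a functional
#' change on recruitment; edge weight is the number of such hits and each
#' edge carries the mean E-value of its hits and the corresponding bin.
#' Same-function hits feed the node `fc` values, never an edge, so there are
#' no self-loops and the hits split exactly into edge weights plus
#' same-function counts.
#'
#' @param map a `function_hit_map`.
#' @param binning an [evalue_binning()] for edge mean E-values.
#' @param mean_mode `"geometric"` (default; the mean of log10 E-values,
#'   exponentiated — natural for quantities spanning many orders of
#'   magnitude) or `"arithmetic"`.
#' @param pm_keys optional character vector of grouping keys present on the
#'   PM side (e.g. `unique(ec_key(pm_catalog$ec, level))`); used to flag
#'   nodes absent from PM.
#' @return object of class `change_graph`: list with tibbles `nodes` (`key`,
#'   `n_hits`, `n_same`, `fc`, `present_in_pm`) and `edges` (`from`, `to`,
#'   `weight`, `mean_evalue`, `bin`), plus `level`, `binning`, `mean_mode`.
#'   Node and edge orderings are lexicographic, so exports are reproducible.
#' @export
build_change_graph <- function(map, binning = evalue_binning(),
                               mean_mode = c("geometric", "arithmetic"),
                               pm_keys = NULL) {
  stopifnot(inherits(map, "function_hit_map"))
  mean_mode <- match.arg(mean_mode)
  tab <- tibble::as_tibble(map)

  fc <- functional_conservation(map)
  node_keys <- sort(unique(c(fc$key, tab$pm_key[!tab$same])), method = "radix")
  nodes <- tibble::tibble(key = node_keys) |>
    dplyr::left_join(tibble::as_tibble(fc), by = "key") |>
    dplyr::mutate(
      n_hits = dplyr::coalesce(.data$n_hits, 0L),
      n_same = dplyr::coalesce(.data$n_same, 0L),
      present_in_pm = if (is.null(pm_keys)) {
        .data$key %in% unique(tab$pm_key)
      } else {
        .data$key %in% pm_keys
      }
    )

  mean_fun <- if (mean_mode == "geometric") {
    function(e) 10^mean(log10(e))
  } else {
    mean
  }
  edges <- tab |>
    dplyr::filter(!.data$same) |>
    dplyr::group_by(from = .data$pm_key, to = .data$sm_key) |>
    dplyr::summarise(
      weight = dplyr::n(),
      mean_evalue = mean_fun(.data$evalue),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin = bin_evalue(.data$mean_evalue, binning)) |>
    dplyr::arrange(.data$from, .data$to)

  structure(
    list(
      nodes = nodes, edges = edges, level = map_level(map),
      binning = binning, mean_mode = mean_mode
    ),
    class = "change_graph"
  )
}

#' @export
print.change_graph <- function(x, ...) {
  cat(
    "# change_graph at level '", x$level, "': ", nrow(x$nodes),
    " nodes, ", nrow(x$edges), " directed edges\n",
    sep = ""
  )
  invisible(x)
}

#' Convert a change graph to an igraph object
#'
#' @param graph a `change_graph`.
#' @return an [igraph::graph] with node attributes `n_hits`, `n_same`, `fc`,
#'   `present_in_pm` and edge attributes `weight`, `mean_evalue`, `bin`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "change_graph"))
  igraph::graph_from_data_frame(
    d = as.data.frame(graph$edges),
    directed = TRUE,
    vertices = as.data.frame(graph$nodes)
  )
}

#' Export a change graph
#'
#' `graphml` preserves all node and edge attributes (lossless; a write/read
#' round-trip reconstructs the graph). `sif` carries topology only, with the
#' interaction type `changes_to`. `edge_tsv` writes one row per edge with all
#' edge attributes.
#'
#' @param graph a `change_graph`.
#' @param path output file.
#' @param format `"graphml"`, `"sif"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "edge_tsv")) {
  stopifnot(inherits(graph, "change_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(graph$edges) > 0) {
      paste(graph$edges$from, "changes_to", graph$edges$to, sep = "\t")
    } else {
      character()
    }
    isolated <- setdiff(graph$nodes$key, c(graph$edges$from, graph$edges$to))
    writeLines(c(lines, isolated), path)
  } else {
    readr::write_tsv(graph$edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a GraphML export back into a change graph
#'
#' @param path a GraphML file written by [export_graph()].
#' @param level the EC level the graph was built at.
#' @return a `change_graph` (binning metadata is not stored in GraphML and
#'   is restored to the default).
#' @export
read_change_graph <- function(path, level = "full") {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::as_tibble(igraph::as_data_frame(g, what = "vertices")) |>
    dplyr::transmute(
      key = .data$name,
      n_hits = as.integer(.data$n_hits),
      n_same = as.integer(.data$n_same),
      fc = as.numeric(.data$fc),
      present_in_pm = as.logical(.data$present_in_pm)
    ) |>
    dplyr::arrange(.data$key)
  edges <- tibble::as_tibble(igraph::as_data_frame(g, what = "edges")) |>
    dplyr::transmute(
      from = .data$from, to = .data$to,
      weight = as.integer(.data$weight),
      mean_evalue = as.numeric(.data$mean_evalue),
      bin = as.character(.data$bin)
    ) |>
    dplyr::arrange(.data$from, .data$to)
  structure(
    list(
      nodes = nodes, edges = edges, level = level,
      binning = evalue_binning(), mean_mode = "geometric"
    ),
    class = "change_graph"
  )
}
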