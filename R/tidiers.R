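#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a change graph into its edge table
#'
#' @param x a `change_graph`.
#' @param ... unused.
#' @return tibble with one row per directed functional-change edge: `from`,
#'   `to`, `weight`, `mean_evalue`, `bin`.
#' @export
tidy.change_graph <- function(x, ...) {
  x$edges
}

#' One-row summary of a change graph
#'
#' @param x a `change_graph`.
#' @param ... unused.
#' @return tibble: `level`, `n_nodes`, `n_edges`, `total_edge_weight`
#'   (function-changing hits), `total_same_hits` (function-keeping hits),
#'   `n_absent_in_pm` (nodes with no PM occurrence).
#' @export
glance.change_graph <- function(x, ...) {
  tibble::tibble(
    level = x$level,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    total_edge_weight = sum(x$edges$weight),
    total_same_hits = sum(x$nodes$n_same),
    n_absent_in_pm = sum(!x$nodes$present_in_pm)
  )
}

#' Tidy a flexibility summary into per-category rows
#'
#' @param x a `flex_summary`.
#' @param ... unused.
#' @return tibble `category`, `n`, `fraction`.
#' @export
tidy.flex_summary <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row overview of a flexibility summary
#'
#' @param x a `flex_summary`.
#' @param ... unused.
#' @return tibble: `level`, `n_keys`, `n_total`, and one
#'   `frac_<category>` column per category.
#' @export
glance.flex_summary <- function(x, ...) {
  wide <- stats::setNames(
    as.list(x$fraction),
    paste0("frac_", tolower(as.character(x$category)))
  )
  dplyr::bind_cols(
    tibble::tibble(
      level = attr(x, "level"),
      n_keys = attr(x, "n_keys"),
      n_total = attr(x, "n_total")
    ),
    tibble::as_tibble(wide)
  )
}
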