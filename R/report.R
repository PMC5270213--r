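html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

gene_link <- function(gene_id, link_template) {
  if (!grepl("{gene_id}", link_template, fixed = TRUE)) {
    stop("link_template lacks the {gene_id} placeholder", call. = FALSE)
  }
  vapply(gene_id, function(g) {
    sub("{gene_id}", g, link_template, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

#' Assemble one report entry for a BGC homolog
#'
#' Bundles everything one putative PM homolog contributes to a per-cluster
#' report: the SM query annotation, the homolog's annotation, the hit
#' E-value, its labeled gene neighborhood and the pathway summary rows.
#'
#' @param sm_annotation display string of the SM query enzyme (id, product,
#'   EC).
#' @param homolog_annotation display string of the putative PM homolog.
#' @param evalue BLAST E-value of the pair.
#' @param neighborhood a labeled `gene_neighborhood`.
#' @param pathways tibble from [summarize_pathways()].
#' @return list of class `report_entry`.
#' @export
report_entry <- function(sm_annotation, homolog_annotation, evalue,
                         neighborhood, pathways) {
  structure(
    list(
      sm_annotation = sm_annotation,
      homolog_annotation = homolog_annotation,
      evalue = evalue,
      neighborhood = neighborhood,
      pathways = pathways
    ),
    class = "report_entry"
  )
}

#' Render a BGC-specific HTML report
#'
#' Produces a deterministic, self-contained HTML page for one biosynthetic
#' gene cluster: one block per homolog entry, each with the header line
#' `BGC; SM query <-> hit; E-value`, the labeled neighborhood table (P/S
#' flags, gene annotation hyperlinked into an external gene database) and
#' the `n_outer/n_inner` pathway summary. Identical input yields
#' byte-identical output: no timestamps, stable ordering.
#'
#' @param bgc_id identifier of the cluster the page describes.
#' @param entries list of [report_entry()] objects (may be empty).
#' @param link_template URL pattern with a `{gene_id}` placeholder used to
#'   hyperlink every gene row.
#' @param path optional output file; when given, the page is written there.
#' @return the HTML document as a single character string (invisibly when
#'   `path` is given).
#' @export
render_report <- function(bgc_id, entries,
                          link_template = "https://www.genome.jp/dbget-bin/www_bget?{gene_id}",
                          path = NULL) {
  stopifnot(is.list(entries))
  # validate the template up front even for empty pages
  gene_link("x", link_template)
  body <- if (length(entries) == 0) {
    "<p>No putative PM homologs found for this cluster.</p>"
  } else {
    paste(vapply(entries, render_entry,
      character(1),
      link_template = link_template
    ), collapse = "\n")
  }
  doc <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", html_escape(bgc_id), " - genomic neighborhoods</title>\n",
    "</head>\n<body>\n",
    "<h1>", html_escape(bgc_id), "</h1>\n",
    body,
    "\n</body>\n</html>\n"
  )
  if (!is.null(path)) {
    writeLines(doc, path, sep = "", useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

render_entry <- function(entry, link_template) {
  stopifnot(inherits(entry, "report_entry"))
  nh <- entry$neighborhood
  anchor <- attr(nh, "anchor")
  header <- sprintf(
    "%s &harr; %s; E-value %s",
    html_escape(entry$sm_annotation),
    html_escape(entry$homolog_annotation),
    format(entry$evalue)
  )
  rows <- vapply(seq_len(nrow(nh)), function(i) {
    ann <- paste0(
      nh$gene_id[i], " ", nh$product[i],
      if (nzchar(nh$ec[i])) paste0(" (EC ", nh$ec[i], ")") else ""
    )
    sprintf(
      "<tr%s><td>%s</td><td>%s</td><td><a href=\"%s\">%s</a></td></tr>",
      if (nh$gene_id[i] == anchor) " class=\"anchor\"" else "",
      if (nh$label_P[i]) "P" else "",
      if (nh$label_S[i]) "S" else "",
      html_escape(gene_link(nh$gene_id[i], link_template)),
      html_escape(ann)
    )
  }, character(1))
  pw <- entry$pathways
  pw_rows <- if (nrow(pw) == 0) {
    "<li>none</li>"
  } else {
    vapply(seq_len(nrow(pw)), function(i) {
      sprintf(
        "<li>%d/%d %s%s</li>",
        pw$n_outer[i], pw$n_inner[i], html_escape(pw$pathway_id[i]),
        if (!is.na(pw$pathway_name[i])) {
          paste0(" ", html_escape(pw$pathway_name[i]))
        } else {
          ""
        }
      )
    }, character(1))
  }
  paste0(
    "<h2>", header, "</h2>\n",
    "<table border=\"1\">\n",
    "<tr><th>E_PM</th><th>K_SM</th><th>Annotation</th></tr>\n",
    paste(rows, collapse = "\n"), "\n</table>\n",
    "<h3>Pathways in &plusmn;", attr(nh, "k"), "/&plusmn;2 neighborhood</h3>\n",
    "<ul>\n", paste(pw_rows, collapse = "\n"), "\n</ul>"
  )
}
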