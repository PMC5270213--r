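#' Assemble a pipeline run configuration
#'
#' A run configuration names the input files and the analysis parameters for
#' the staged pipeline ([run_spectrum()], [run_flexibility()],
#' [run_neighborhoods()], [run_pipeline()]). It can also be read from a YAML
#' file with [read_run_config()]; every field is echoed verbatim into the
#' run manifest.
#'
#' @param pm_catalog,sm_catalog paths to the PM and SM catalog TSVs.
#' @param hits path to the homology hit table (may be `NULL` for
#'   spectrum-only runs).
#' @param genomes path to the genome gene-order table (neighborhood stage).
#' @param pathway_map path to the pathway id/name TSV.
#' @param pairs data frame or TSV path of neighborhood jobs: columns
#'   `bgc_id`, `sm_gene_id`, `anchor_id`, `evalue`.
#' @param out_dir output directory.
#' @param levels EC levels to analyze.
#' @param evalue_cutoff,length_tolerance homolog filter settings.
#' @param pairing frequency-correlation pairing policy.
#' @param flag_threshold overrepresentation flagging threshold.
#' @param k_outer,k_inner neighborhood window half-widths.
#' @param sm_pathway_id pathway id carrying the S label.
#' @param link_template gene hyperlink pattern for HTML reports.
#' @return list of class `run_config`.
#' @export
run_config <- function(pm_catalog, sm_catalog, hits = NULL, genomes = NULL,
                       pathway_map = NULL, pairs = NULL,
                       out_dir = "smrecruit_out",
                       levels = c("class", "subdivision", "full"),
                       evalue_cutoff = 1e-20, length_tolerance = 0.30,
                       pairing = "union_zero_fill", flag_threshold = 20,
                       k_outer = 10, k_inner = 2,
                       sm_pathway_id = NULL,
                       link_template = "https://www.genome.jp/dbget-bin/www_bget?{gene_id}") {
  levels <- match.arg(levels, ec_levels(), several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(run_config, raw)
}

check_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop("[", what, "] input file missing: ",
      if (is.null(path)) "(not configured)" else path,
      call. = FALSE
    )
  }
  invisible(path)
}

num_fmt <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "g", digits = 6))
}

write_stage_tsv <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double), num_fmt))
  readr::write_tsv(df, path, progress = FALSE)
  path
}

load_filtered <- function(path, role, what) {
  check_input(path, what)
  apply_inclusion_filters(read_catalog(path, role = role))
}

#' Run the spectrum stage
#'
#' Loads and filters both catalogs, then writes per-level frequency tables,
#' overrepresentation ratios, shared/exclusive function sets and the
#' frequency correlation, plus a run manifest.
#'
#' @param config a `run_config`.
#' @return invisible list of per-level results (`frequencies`, `overrep`,
#'   `sets`, `r_squared`).
#' @export
run_spectrum <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pm <- load_filtered(config$pm_catalog, "pm", "spectrum")
  sm <- load_filtered(config$sm_catalog, "sm", "spectrum")
  results <- list()
  for (level in config$levels) {
    f_pm <- ec_frequencies(pm, level)
    f_sm <- ec_frequencies(sm, level)
    ov <- overrep_ratios(f_sm, f_pm, flag_threshold = config$flag_threshold)
    sets <- shared_exclusive_functions(sm, pm, level)
    r2 <- tryCatch(
      frequency_correlation(f_sm, f_pm, pairing = config$pairing),
      error = function(e) NA_real_
    )
    write_stage_tsv(
      tibble::as_tibble(f_pm),
      file.path(config$out_dir, paste0("freq_pm_", level, ".tsv"))
    )
    write_stage_tsv(
      tibble::as_tibble(f_sm),
      file.path(config$out_dir, paste0("freq_sm_", level, ".tsv"))
    )
    write_stage_tsv(
      tibble::as_tibble(ov),
      file.path(config$out_dir, paste0("overrep_", level, ".tsv"))
    )
    set_tbl <- tibble::tibble(
      key = c(sets$shared, sets$sm_only, sets$pm_only),
      status = rep(
        c("shared", "sm_only", "pm_only"),
        c(length(sets$shared), length(sets$sm_only), length(sets$pm_only))
      )
    ) |> dplyr::arrange(.data$key)
    write_stage_tsv(
      set_tbl,
      file.path(config$out_dir, paste0("function_sets_", level, ".tsv"))
    )
    results[[level]] <- list(
      f_pm = f_pm, f_sm = f_sm, overrep = ov, sets = sets, r_squared = r2
    )
  }
  write_manifest(config, "spectrum", list(
    n_pm = nrow(pm), n_sm = nrow(sm),
    filter_log_pm = as.list(filter_log(pm)),
    filter_log_sm = as.list(filter_log(sm))
  ))
  invisible(results)
}

#' Run the homology/flexibility stage
#'
#' Filters the hit table, and per level writes the EC hits-counts table,
#' the classification with its summary, the functional-conservation table,
#' and the functional-change graph (GraphML, SIF and edge TSV).
#'
#' @param config a `run_config`.
#' @return invisible list of per-level results (`map`, `classification`,
#'   `summary`, `fc`, `graph`).
#' @export
run_flexibility <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  check_input(config$hits, "flexibility")
  pm_raw <- read_catalog(check_input(config$pm_catalog, "flexibility"), role = "pm")
  sm_raw <- read_catalog(check_input(config$sm_catalog, "flexibility"), role = "sm")
  pm <- apply_inclusion_filters(pm_raw)
  sm <- apply_inclusion_filters(sm_raw)
  hits <- read_hit_table(config$hits)
  kept <- filter_hits(hits,
    query_catalog = sm_raw, subject_catalog = pm_raw,
    evalue_cutoff = config$evalue_cutoff,
    length_tolerance = config$length_tolerance
  )
  if (nrow(kept) == 0) {
    warning("no hits survive the filters; flexibility outputs are empty",
      call. = FALSE
    )
  }
  results <- list()
  for (level in config$levels) {
    map <- function_hit_map(kept, sm, pm, level = level)
    cls <- classify_functions(map)
    fc <- functional_conservation(map)
    graph <- build_change_graph(map,
      pm_keys = unique(stats::na.omit(ec_key(pm$ec, level)))
    )
    write_stage_tsv(
      ec_hits_counts(map),
      file.path(config$out_dir, paste0("ec_hits_counts_", level, ".tsv"))
    )
    write_stage_tsv(
      tibble::as_tibble(cls),
      file.path(config$out_dir, paste0("classification_", level, ".tsv"))
    )
    write_stage_tsv(
      tibble::as_tibble(fc),
      file.path(config$out_dir, paste0("fc_", level, ".tsv"))
    )
    export_graph(graph,
      file.path(config$out_dir, paste0("change_graph_", level, ".graphml")),
      format = "graphml"
    )
    export_graph(graph,
      file.path(config$out_dir, paste0("change_graph_", level, ".sif")),
      format = "sif"
    )
    export_graph(graph,
      file.path(config$out_dir, paste0("change_graph_", level, ".edges.tsv")),
      format = "edge_tsv"
    )
    summary <- if (nrow(cls) > 0) summarize_classification(cls) else NULL
    if (!is.null(summary)) {
      jsonlite::write_json(
        list(
          level = level,
          counts = as.list(stats::setNames(summary$n, as.character(summary$category))),
          fractions = as.list(stats::setNames(summary$fraction, as.character(summary$category))),
          n_keys = attr(summary, "n_keys"),
          evalue_cutoff = config$evalue_cutoff,
          length_tolerance = config$length_tolerance
        ),
        file.path(config$out_dir, paste0("classification_summary_", level, ".json")),
        auto_unbox = TRUE, digits = NA
      )
    }
    results[[level]] <- list(
      map = map, classification = cls, summary = summary, fc = fc, graph = graph
    )
  }
  write_manifest(config, "flexibility", list(
    n_hits_in = nrow(hits), n_hits_kept = nrow(kept),
    n_rejected = nrow(hit_rejections(kept))
  ))
  invisible(results)
}

#' Run the neighborhood stage
#'
#' For every (BGC, SM enzyme, putative PM homolog) job in the pairing table,
#' extracts the gene neighborhood, assigns P/S labels, summarizes pathways,
#' and writes one HTML report per BGC plus a tally TSV.
#'
#' @param config a `run_config` with `genomes`, `pathway_map` and `pairs`
#'   set.
#' @return invisible tibble of per-anchor tallies.
#' @export
run_neighborhoods <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_table(check_input(config$genomes, "neighborhoods"))
  pm <- load_filtered(config$pm_catalog, "pm", "neighborhoods")
  pathway_map <- if (!is.null(config$pathway_map)) {
    read_pathway_map(config$pathway_map)
  } else {
    NULL
  }
  pairs <- config$pairs
  if (is.character(pairs)) {
    pairs <- readr::read_tsv(pairs,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
  }
  pm_keys <- unique(pm$ec[ec_complete_at(pm$ec, "full")])
  tallies <- list()
  if (is.null(pairs) || nrow(pairs) == 0) {
    render_report("index", list(), config$link_template,
      path = file.path(config$out_dir, "index.html")
    )
  } else {
    pairs$evalue <- as.numeric(pairs$evalue)
    for (bgc in sort(unique(pairs$bgc_id))) {
      sub <- pairs[pairs$bgc_id == bgc, , drop = FALSE]
      sub <- sub[order(sub$sm_gene_id, sub$anchor_id), , drop = FALSE]
      entries <- list()
      for (i in seq_len(nrow(sub))) {
        nh <- extract_neighborhood(genome, sub$anchor_id[i], k = config$k_outer)
        nh <- assign_labels(nh,
          pm_keys = pm_keys,
          sm_pathway_id = config$sm_pathway_id
        )
        pw <- summarize_pathways(nh,
          k_inner = config$k_inner,
          pathway_map = pathway_map
        )
        entries[[i]] <- report_entry(
          sm_annotation = paste0(bgc, "; SM* ", sub$sm_gene_id[i]),
          homolog_annotation = paste0("PM ", sub$anchor_id[i]),
          evalue = sub$evalue[i],
          neighborhood = nh,
          pathways = pw
        )
        tallies[[length(tallies) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(
            bgc_id = bgc, sm_gene_id = sub$sm_gene_id[i],
            anchor_id = sub$anchor_id[i]
          ),
          summarize_labels(nh)
        )
      }
      render_report(bgc, entries, config$link_template,
        path = file.path(config$out_dir, paste0(bgc, ".html"))
      )
    }
  }
  tallies <- if (length(tallies) > 0) {
    dplyr::bind_rows(tallies)
  } else {
    tibble::tibble(
      bgc_id = character(), sm_gene_id = character(),
      anchor_id = character(), n_P = integer(), n_S = integer()
    )
  }
  readr::write_tsv(tallies, file.path(config$out_dir, "neighborhood_tallies.tsv"),
    progress = FALSE
  )
  write_manifest(config, "neighborhoods", list(n_jobs = nrow(tallies)))
  invisible(tallies)
}

#' Run every configured stage
#'
#' @param config a `run_config`.
#' @return invisible list with the per-stage results.
#' @export
run_pipeline <- function(config) {
  out <- list(spectrum = run_spectrum(config))
  if (!is.null(config$hits)) out$flexibility <- run_flexibility(config)
  if (!is.null(config$genomes)) out$neighborhoods <- run_neighborhoods(config)
  invisible(out)
}

write_manifest <- function(config, stage, counts) {
  inputs <- Filter(
    function(p) is.character(p) && length(p) == 1 && file.exists(p),
    config[c("pm_catalog", "sm_catalog", "hits", "genomes", "pathway_map")]
  )
  digests <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("smrecruit")),
    config = config[setdiff(names(config), "pairs")],
    input_md5 = digests,
    counts = counts
  )
  jsonlite::write_json(manifest,
    file.path(config$out_dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(manifest)
}
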