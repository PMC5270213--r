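#' Configuration of the synthetic-data generator
#'
#' The generator emulates the study design end to end: a PM side of several
#' BGC-free genomes, an SM side of biosynthetic gene clusters, homolog
#' families planted across the two sides with controlled functional makeup,
#' a BLAST-style hit table whose E-values and lengths straddle the filter
#' thresholds, and per-genome gene-order tables with operon-like runs of
#' co-pathway genes plus an embedded BGC span.
#'
#' @param n_pm_collections number of PM genomes (default 15, the size of a
#'   BGC-free genome panel).
#' @param genes_per_collection background enzymes per genome (default 65, so
#'   the default PM side holds about a thousand records).
#' @param n_bgcs number of BGCs on the SM side.
#' @param enzymes_per_bgc background enzymes per BGC.
#' @param ec_profile named per-class weights used to sample background EC
#'   numbers; defaults approximate a primary-metabolism class spectrum
#'   (transferases most abundant, isomerases least).
#' @param family_design list of planted homolog families; see
#'   [default_family_design()].
#' @param n_pm_per_function,n_sm_per_function family members planted per PM
#'   (SM) function.
#' @param evalue_range_family E-value range (log-uniform) for within-family
#'   hits; must lie at or below the default 1e-20 acceptance cutoff.
#' @param evalue_range_decoy E-value range for cross-family decoy hits; must
#'   lie above 1e-20 (so decoys appear only under the relaxed 1e-10
#'   control).
#' @param n_decoy_hits,n_length_decoys number of E-value decoys and of
#'   below-cutoff hits whose subject length violates the 30 percent rule.
#' @param length_range background protein length range (amino acids).
#' @param length_jitter within-family length jitter as a fraction of the
#'   family's base length; 0.10 keeps all family pairs within the length
#'   tolerance.
#' @param operon_lengths admissible operon run lengths in the genome tables.
#' @param fraction_no_ec,fraction_multi_ec fractions of background records
#'   emitted without an EC or with two ECs (removed by the inclusion
#'   filters; the filter log must recover them exactly).
#' @param sm_pathway_id pathway id standing for the species-level
#'   "Biosynthesis of secondary metabolites" map.
#' @param k_outer,k_inner neighborhood window half-widths.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_pm_collections = 15,
                              genes_per_collection = 65,
                              n_bgcs = 20,
                              enzymes_per_bgc = 5,
                              ec_profile = c(
                                "1" = 18.7, "2" = 35.3, "3" = 17.3,
                                "4" = 10.7, "5" = 6.7, "6" = 11.4
                              ),
                              family_design = default_family_design(),
                              n_pm_per_function = 2,
                              n_sm_per_function = 2,
                              evalue_range_family = c(1e-40, 1e-21),
                              evalue_range_decoy = c(1e-18, 1e-11),
                              n_decoy_hits = 30,
                              n_length_decoys = 10,
                              length_range = c(150, 600),
                              length_jitter = 0.10,
                              operon_lengths = 3:4,
                              fraction_no_ec = 0.05,
                              fraction_multi_ec = 0.05,
                              sm_pathway_id = "map01110",
                              k_outer = 10, k_inner = 2) {
  stopifnot(
    all(ec_profile >= 0), length_jitter >= 0, length_jitter < 1,
    evalue_range_family[2] <= 1e-20, evalue_range_decoy[1] > 1e-20,
    fraction_no_ec >= 0, fraction_multi_ec >= 0,
    fraction_no_ec + fraction_multi_ec < 1
  )
  for (fam in family_design) {
    if (length(fam$sm_functions) == 0 || length(fam$pm_functions) == 0) {
      stop("infeasible family design: empty function set in ", fam$family_id,
        call. = FALSE
      )
    }
  }
  if (exists("fam", inherits = FALSE)) rm(fam)
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted homolog family design
#'
#' Eleven families spanning the three functional-makeup categories: six
#' monofunctional families (SM function identical to the PM function, one
#' per EC class), three multifunctional families whose PM side carries the
#' SM function plus one additional function, and two fully changed families
#' whose PM homologs all catalyze something else — one of them the
#' isochorismate-synthase constellation (SM 5.4.4.2 with PM homologs
#' 2.6.1.85 and 4.1.3.27).
#'
#' @return list of family specifications (`family_id`, `sm_functions`,
#'   `pm_functions`, `category`).
#' @export
default_family_design <- function() {
  fam <- function(id, sm, pm, category) {
    list(family_id = id, sm_functions = sm, pm_functions = pm, category = category)
  }
  list(
    fam("mono_ox", "1.1.1.1", "1.1.1.1", "ALL_SAME"),
    fam("mono_tr", "2.3.1.9", "2.3.1.9", "ALL_SAME"),
    fam("mono_hy", "3.1.3.16", "3.1.3.16", "ALL_SAME"),
    fam("mono_ly", "4.2.1.20", "4.2.1.20", "ALL_SAME"),
    fam("mono_is", "5.3.1.24", "5.3.1.24", "ALL_SAME"),
    fam("mono_li", "6.3.4.19", "6.3.4.19", "ALL_SAME"),
    fam("mixed_dc", "4.1.1.48", c("4.1.1.48", "2.4.2.18"), "MIXED"),
    fam("mixed_lig", "2.7.7.58", c("2.7.7.58", "6.2.1.26"), "MIXED"),
    fam("mixed_mono", "1.14.13.9", c("1.14.13.9", "1.13.11.6"), "MIXED"),
    fam("ics", "5.4.4.2", c("2.6.1.85", "4.1.3.27"), "ALL_DIFF"),
    fam("prot", "3.4.22.10", "3.4.21.26", "ALL_DIFF")
  )
}

background_ec_pool <- function() {
  pool <- expand.grid(
    class = 1:6, subclass = 1:2, subdivision = 1:3, serial = 31:32
  )
  tibble::tibble(
    ec = paste(pool$class, pool$subclass, pool$subdivision, pool$serial, sep = "."),
    class = as.character(pool$class)
  )
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif_log <- function(n, range) {
  10^stats::runif(n, log10(range[1]), log10(range[2]))
}

#' Simulate a complete input bundle with planted ground truth
#'
#' Deterministic given `seed`: the same seed yields an identical bundle.
#' Within-family hit E-values are drawn log-uniformly below the default
#' acceptance cutoff and member lengths within the length tolerance, so
#' every family hit survives the filters; decoy hits carry above-cutoff
#' E-values (visible only under the relaxed control cutoff) or
#' tolerance-violating subject lengths. No-EC and multi-EC records are
#' injected at the configured fractions.
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed.
#' @return list of class `sim_bundle`: tibbles `pm_catalog`, `sm_catalog`,
#'   `hits` (12-column hit-table layout), `genomes` (one gene-order table
#'   spanning all PM genomes), `pathway_map`, and `truth` (planted
#'   structure: `members`, `hits_planted`, injection counts, anchors).
#' @export
simulate_bundle <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(seed, build_bundle(config, seed))
}

build_bundle <- function(cfg, seed) {
  pool <- background_ec_pool()
  wts <- cfg$ec_profile[pool$class]

  sample_ecs <- function(n) pool$ec[sample.int(nrow(pool), n, replace = TRUE, prob = wts)]
  sample_len <- function(n) sample(seq(cfg$length_range[1], cfg$length_range[2]), n, replace = TRUE)

  pm_ids <- sprintf("genome_%02d", seq_len(cfg$n_pm_collections))
  sm_ids <- sprintf("BGC%03d", seq_len(cfg$n_bgcs))

  # --- background records -------------------------------------------------
  n_pm_bg <- cfg$n_pm_collections * cfg$genes_per_collection
  pm_bg <- tibble::tibble(
    gene_id = sprintf("pmg_%04d", seq_len(n_pm_bg)),
    collection_id = rep(pm_ids, each = cfg$genes_per_collection),
    species_tax = rep(sprintf("tax_%02d", seq_len(cfg$n_pm_collections)),
      each = cfg$genes_per_collection
    ),
    ec = sample_ecs(n_pm_bg),
    length = sample_len(n_pm_bg),
    product = "background enzyme"
  )
  n_sm_bg <- cfg$n_bgcs * cfg$enzymes_per_bgc
  sm_bg <- tibble::tibble(
    gene_id = sprintf("smg_%04d", seq_len(n_sm_bg)),
    collection_id = rep(sm_ids, each = cfg$enzymes_per_bgc),
    species_tax = rep(sprintf("smtax_%02d", seq_len(cfg$n_bgcs)),
      each = cfg$enzymes_per_bgc
    ),
    ec = sample_ecs(n_sm_bg),
    length = sample_len(n_sm_bg),
    product = "cluster enzyme"
  )

  # --- inject no-EC / multi-EC records (removed later by the filters) -----
  inject <- function(bg) {
    n <- nrow(bg)
    n_no <- round(cfg$fraction_no_ec * n)
    n_multi <- round(cfg$fraction_multi_ec * n)
    idx <- sample.int(n, n_no + n_multi)
    bg$ec[idx[seq_len(n_no)]] <- ""
    if (n_multi > 0) {
      multi_idx <- idx[n_no + seq_len(n_multi)]
      bg$ec[multi_idx] <- paste(sample_ecs(n_multi), sample_ecs(n_multi), sep = ";")
    }
    list(bg = bg, n_no_ec = n_no, n_multi_ec = n_multi)
  }
  pm_inj <- inject(pm_bg)
  sm_inj <- inject(sm_bg)
  pm_bg <- pm_inj$bg
  sm_bg <- sm_inj$bg

  # --- planted family members --------------------------------------------
  members <- list()
  pm_slot <- 0L
  sm_slot <- 0L
  for (fam in cfg$family_design) {
    base_len <- sample(200:500, 1)
    jitter_len <- function(n) {
      round(base_len * stats::runif(n, 1 - cfg$length_jitter, 1 + cfg$length_jitter))
    }
    for (ecs in fam$pm_functions) {
      for (j in seq_len(cfg$n_pm_per_function)) {
        pm_slot <- pm_slot + 1L
        members[[length(members) + 1L]] <- tibble::tibble(
          family_id = fam$family_id, side = "pm",
          gene_id = sprintf("fam_pm_%03d", pm_slot),
          collection_id = pm_ids[(pm_slot - 1L) %% cfg$n_pm_collections + 1L],
          ec = ecs, length = jitter_len(1)
        )
      }
    }
    for (ecs in fam$sm_functions) {
      for (j in seq_len(cfg$n_sm_per_function)) {
        sm_slot <- sm_slot + 1L
        members[[length(members) + 1L]] <- tibble::tibble(
          family_id = fam$family_id, side = "sm",
          gene_id = sprintf("fam_sm_%03d", sm_slot),
          collection_id = sm_ids[(sm_slot - 1L) %% cfg$n_bgcs + 1L],
          ec = ecs, length = jitter_len(1)
        )
      }
    }
  }
  members <- dplyr::bind_rows(members)

  pm_members <- members[members$side == "pm", , drop = FALSE]
  sm_members <- members[members$side == "sm", , drop = FALSE]
  pm_catalog <- dplyr::bind_rows(
    pm_bg,
    tibble::tibble(
      gene_id = pm_members$gene_id,
      collection_id = pm_members$collection_id,
      species_tax = sprintf(
        "tax_%02d",
        match(pm_members$collection_id, pm_ids)
      ),
      ec = pm_members$ec,
      length = pm_members$length,
      product = paste0("family enzyme (", pm_members$family_id, ")")
    )
  )
  sm_catalog <- dplyr::bind_rows(
    sm_bg,
    tibble::tibble(
      gene_id = sm_members$gene_id,
      collection_id = sm_members$collection_id,
      species_tax = sprintf("smtax_%02d", match(sm_members$collection_id, sm_ids)),
      ec = sm_members$ec,
      length = sm_members$length,
      product = paste0("family enzyme (", sm_members$family_id, ")")
    )
  )

  # --- planted hits -------------------------------------------------------
  fam_hits <- list()
  for (fam in cfg$family_design) {
    fp <- pm_members[pm_members$family_id == fam$family_id, , drop = FALSE]
    fs <- sm_members[sm_members$family_id == fam$family_id, , drop = FALSE]
    grid <- expand.grid(q = seq_len(nrow(fs)), s = seq_len(nrow(fp)))
    fam_hits[[fam$family_id]] <- tibble::tibble(
      query_id = fs$gene_id[grid$q],
      subject_id = fp$gene_id[grid$s],
      sm_ec = fs$ec[grid$q],
      pm_ec = fp$ec[grid$s],
      qlen = fs$length[grid$q],
      slen = fp$length[grid$s],
      evalue = runif_log(nrow(grid), cfg$evalue_range_family),
      kind = "family",
      kept_default = TRUE
    )
  }
  fam_hits <- dplyr::bind_rows(fam_hits)

  # decoy subjects: background PM genes that kept a single EC
  bg_ok <- pm_bg[!grepl(";", pm_bg$ec, fixed = TRUE) & nzchar(pm_bg$ec), , drop = FALSE]
  qpick <- sm_members[sample.int(nrow(sm_members), cfg$n_decoy_hits, replace = TRUE), ]
  spick <- bg_ok[sample.int(nrow(bg_ok), cfg$n_decoy_hits, replace = TRUE), ]
  ok_len <- abs(spick$length - qpick$length) / qpick$length <= 0.30
  decoys <- tibble::tibble(
    query_id = qpick$gene_id, subject_id = spick$gene_id,
    sm_ec = qpick$ec, pm_ec = spick$ec,
    qlen = qpick$length, slen = spick$length,
    evalue = runif_log(cfg$n_decoy_hits, cfg$evalue_range_decoy),
    kind = as.character(ifelse(ok_len, "decoy_evalue", "decoy_evalue_length")),
    kept_default = FALSE
  )

  qpick2 <- sm_members[sample.int(nrow(sm_members), cfg$n_length_decoys, replace = TRUE), ]
  len_decoys <- list()
  for (i in seq_len(cfg$n_length_decoys)) {
    bad <- bg_ok[abs(bg_ok$length - qpick2$length[i]) / qpick2$length[i] > 0.30, , drop = FALSE]
    if (nrow(bad) == 0) next
    s <- bad[sample.int(nrow(bad), 1), ]
    len_decoys[[i]] <- tibble::tibble(
      query_id = qpick2$gene_id[i], subject_id = s$gene_id,
      sm_ec = qpick2$ec[i], pm_ec = s$ec,
      qlen = qpick2$length[i], slen = s$length,
      evalue = runif_log(1, cfg$evalue_range_family),
      kind = "decoy_length",
      kept_default = FALSE
    )
  }
  hits_planted <- dplyr::bind_rows(fam_hits, decoys, dplyr::bind_rows(len_decoys)) |>
    dplyr::distinct(.data$query_id, .data$subject_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$query_id, .data$subject_id)

  aln <- pmin(hits_planted$qlen, hits_planted$slen)
  hits <- tibble::tibble(
    query_id = hits_planted$query_id,
    subject_id = hits_planted$subject_id,
    pident = round(stats::runif(nrow(hits_planted), 30, 90), 1),
    aln_len = aln,
    mismatch = round(aln * 0.2),
    gapopen = 1,
    qstart = 1, qend = aln, sstart = 1, send = aln,
    evalue = hits_planted$evalue,
    bitscore = round(-10 * log10(hits_planted$evalue), 1)
  )

  # --- genomes: operon-like runs plus an embedded BGC span ----------------
  pm_pathways <- sprintf("path%03d", 1:10)
  genomes <- list()
  anchors <- list()
  for (gi in seq_along(pm_ids)) {
    gene_rows <- pm_catalog[pm_catalog$collection_id == pm_ids[gi], , drop = FALSE]
    gene_rows <- gene_rows[sample.int(nrow(gene_rows)), , drop = FALSE]
    # contiguous operon runs sharing a pathway
    pw <- character(nrow(gene_rows))
    i <- 1L
    while (i <= nrow(gene_rows)) {
      run <- sample(cfg$operon_lengths, 1)
      pw[i:min(nrow(gene_rows), i + run - 1L)] <- sample(pm_pathways, 1)
      i <- i + run
    }
    gtab <- tibble::tibble(
      replicon_id = pm_ids[gi],
      gene_id = gene_rows$gene_id,
      strand = sample(c("+", "-"), nrow(gene_rows), replace = TRUE),
      product = gene_rows$product,
      ec = gene_rows$ec,
      pathways = pw
    )
    # embed one BGC span (SM genes of a cluster) mid-genome
    bgc <- sm_ids[(gi - 1L) %% cfg$n_bgcs + 1L]
    span_rows <- sm_catalog[sm_catalog$collection_id == bgc, , drop = FALSE]
    span <- tibble::tibble(
      replicon_id = pm_ids[gi],
      gene_id = paste0(span_rows$gene_id, "_g"),
      strand = "+",
      product = span_rows$product,
      ec = span_rows$ec,
      pathways = cfg$sm_pathway_id
    )
    at <- sample(seq_len(nrow(gtab) - 1L), 1)
    gtab <- dplyr::bind_rows(gtab[1:at, ], span, gtab[(at + 1L):nrow(gtab), ])
    gtab$ordinal <- seq_len(nrow(gtab))
    genomes[[gi]] <- gtab[c(
      "replicon_id", "ordinal", "gene_id", "strand",
      "product", "ec", "pathways"
    )]
    fam_here <- pm_members$gene_id[pm_members$collection_id == pm_ids[gi]]
    if (length(fam_here) > 0) {
      anchors[[gi]] <- tibble::tibble(
        collection_id = pm_ids[gi],
        anchor_id = sort(fam_here)[1]
      )
    }
  }
  genomes <- dplyr::bind_rows(genomes)
  anchors <- dplyr::bind_rows(anchors)

  pathway_map <- tibble::tibble(
    pathway_id = c(pm_pathways, cfg$sm_pathway_id),
    pathway_name = c(
      sprintf("Simulated pathway %02d", seq_along(pm_pathways)),
      "Biosynthesis of secondary metabolites"
    )
  )

  structure(
    list(
      pm_catalog = pm_catalog,
      sm_catalog = sm_catalog,
      hits = hits,
      genomes = genomes,
      pathway_map = pathway_map,
      truth = list(
        members = members,
        hits_planted = hits_planted,
        pm_n_no_ec = pm_inj$n_no_ec,
        pm_n_multi_ec = pm_inj$n_multi_ec,
        sm_n_no_ec = sm_inj$n_no_ec,
        sm_n_multi_ec = sm_inj$n_multi_ec,
        anchors = anchors,
        family_design = cfg$family_design
      ),
      config = cfg,
      seed = seed
    ),
    class = "sim_bundle"
  )
}

#' Write a simulated bundle to disk in the ingestion formats
#'
#' Emits `pm_catalog.tsv`, `sm_catalog.tsv`, `hits.tsv` (headerless
#' 12-column hit table), `genomes.tsv`, `pathway_map.tsv` and `truth.json`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(bundle$pm_catalog, file.path(dir, "pm_catalog.tsv"), progress = FALSE)
  readr::write_tsv(bundle$sm_catalog, file.path(dir, "sm_catalog.tsv"), progress = FALSE)
  readr::write_tsv(bundle$hits, file.path(dir, "hits.tsv"),
    col_names = FALSE, progress = FALSE
  )
  readr::write_tsv(bundle$genomes, file.path(dir, "genomes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$pathway_map, file.path(dir, "pathway_map.tsv"), progress = FALSE)
  truth <- bundle$truth
  truth$family_design <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    dataframe = "rows", digits = NA
  )
  invisible(dir)
}
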