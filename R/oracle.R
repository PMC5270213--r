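# Brute-force reference results for a simulated bundle. Everything here is
# computed by plain enumeration over the planted structure (base R string
# splitting, loops, table()) and never calls the pipeline's own EC algebra,
# filtering or grouping code, so tests can compare the two routes.

oracle_key <- function(ec, depth) {
  parts <- strsplit(ec, ".", fixed = TRUE)
  vapply(parts, function(p) {
    head_p <- p[seq_len(depth)]
    if (any(head_p == "-")) NA_character_ else paste(head_p, collapse = ".")
  }, character(1))
}

oracle_depth <- function(level) {
  c(class = 1L, subclass = 2L, subdivision = 3L, full = 4L)[[level]]
}

#' Reference outputs for a simulated bundle, by exhaustive enumeration
#'
#' Recomputes, directly from the planted ground truth and the emitted
#' catalogs, everything the pipeline is expected to produce: the inclusion
#' filter tallies, shared/exclusive function sets, per-key classification
#' categories and counts, rates of functional conservation, and the
#' functional-change edge list. The implementation is independent of the
#' package's analysis code paths (simple loops and string handling), so an
#' exact match between the two is a meaningful end-to-end check.
#'
#' @param bundle a `sim_bundle` from [simulate_bundle()].
#' @param level one of [ec_levels()].
#' @return list: `filter_log_pm`, `filter_log_sm` (expected removal counts),
#'   `shared`, `sm_only`, `pm_only` (key sets at `level`),
#'   `classification` (data frame `key`, `n_hits`, `n_same`, `category`),
#'   `fc` (data frame `key`, `fc`), `edges` (data frame `from`, `to`,
#'   `weight`), `n_kept_hits`.
#' @export
oracle_expected_outputs <- function(bundle, level = "full") {
  stopifnot(inherits(bundle, "sim_bundle"))
  depth <- oracle_depth(level)
  truth <- bundle$truth

  # --- expected filter logs ----------------------------------------------
  count_side <- function(catalog) {
    ecs <- catalog$ec
    n_ec <- integer(length(ecs))
    for (i in seq_along(ecs)) {
      v <- trimws(strsplit(ecs[i], ";", fixed = TRUE)[[1]])
      n_ec[i] <- sum(nzchar(v))
    }
    c(
      n_input = length(ecs), n_removed_no_ec = sum(n_ec == 0),
      n_removed_multi_ec = sum(n_ec > 1), n_kept = sum(n_ec == 1)
    )
  }

  # --- shared / exclusive keys from the emitted catalogs ------------------
  single_ec_keys <- function(catalog) {
    keys <- character(0)
    for (i in seq_len(nrow(catalog))) {
      v <- trimws(strsplit(catalog$ec[i], ";", fixed = TRUE)[[1]])
      v <- v[nzchar(v)]
      if (length(v) != 1) next
      k <- oracle_key(v, depth)
      if (!is.na(k)) keys <- c(keys, k)
    }
    sort(unique(keys), method = "radix")
  }
  sm_keys <- single_ec_keys(bundle$sm_catalog)
  pm_keys <- single_ec_keys(bundle$pm_catalog)

  # --- kept hits and their keys -------------------------------------------
  kept <- truth$hits_planted[truth$hits_planted$kept_default, , drop = FALSE]
  skey <- oracle_key(kept$sm_ec, depth)
  pkey <- oracle_key(kept$pm_ec, depth)
  usable <- !is.na(skey) & !is.na(pkey)
  skey <- skey[usable]
  pkey <- pkey[usable]

  cls_keys <- sort(unique(skey), method = "radix")
  n_hits <- n_same <- integer(length(cls_keys))
  for (i in seq_along(cls_keys)) {
    sel <- skey == cls_keys[i]
    n_hits[i] <- sum(sel)
    n_same[i] <- sum(pkey[sel] == cls_keys[i])
  }
  category <- ifelse(n_same == n_hits, "ALL_SAME",
    ifelse(n_same == 0, "ALL_DIFF", "MIXED")
  )

  # --- change edges --------------------------------------------------------
  diff_sel <- pkey != skey
  if (any(diff_sel)) {
    ed <- as.data.frame(table(from = pkey[diff_sel], to = skey[diff_sel]),
      stringsAsFactors = FALSE
    )
    ed <- ed[ed$Freq > 0, , drop = FALSE]
    names(ed)[3] <- "weight"
    ed <- ed[order(ed$from, ed$to, method = "radix"), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(from = character(), to = character(), weight = integer())
  }

  list(
    filter_log_pm = count_side(bundle$pm_catalog),
    filter_log_sm = count_side(bundle$sm_catalog),
    shared = intersect(sm_keys, pm_keys),
    sm_only = setdiff(sm_keys, pm_keys),
    pm_only = setdiff(pm_keys, sm_keys),
    classification = data.frame(
      key = cls_keys, n_hits = n_hits, n_same = n_same,
      category = category, stringsAsFactors = FALSE
    ),
    fc = data.frame(key = cls_keys, fc = n_same / n_hits, stringsAsFactors = FALSE),
    edges = ed,
    n_kept_hits = length(skey)
  )
}

#' Expected neighborhood label tallies for the planted anchors
#'
#' Counts, by direct enumeration over the emitted genome table, the P and S
#' labels in the window around each planted anchor: P for a gene whose
#' single complete EC occurs in the (filtered) PM catalog, S for a gene
#' mapped to the secondary-metabolites pathway.
#'
#' @param bundle a `sim_bundle`.
#' @return data frame `collection_id`, `anchor_id`, `n_P`, `n_S`.
#' @export
oracle_neighborhood_tallies <- function(bundle) {
  stopifnot(inherits(bundle, "sim_bundle"))
  cfg <- bundle$config
  pm_full <- character(0)
  for (i in seq_len(nrow(bundle$pm_catalog))) {
    v <- trimws(strsplit(bundle$pm_catalog$ec[i], ";", fixed = TRUE)[[1]])
    v <- v[nzchar(v)]
    if (length(v) == 1 && !grepl("-", v, fixed = TRUE)) pm_full <- c(pm_full, v)
  }
  pm_full <- unique(pm_full)
  anchors <- bundle$truth$anchors
  res <- anchors
  res$n_P <- res$n_S <- NA_integer_
  for (a in seq_len(nrow(anchors))) {
    g <- bundle$genomes[bundle$genomes$replicon_id == anchors$collection_id[a], , drop = FALSE]
    g <- g[order(g$ordinal), , drop = FALSE]
    pos <- which(g$gene_id == anchors$anchor_id[a])
    win <- g[max(1, pos - cfg$k_outer):min(nrow(g), pos + cfg$k_outer), , drop = FALSE]
    p_cnt <- 0L
    s_cnt <- 0L
    for (i in seq_len(nrow(win))) {
      v <- trimws(strsplit(win$ec[i], ";", fixed = TRUE)[[1]])
      v <- v[nzchar(v)]
      complete <- v[!grepl("-", v, fixed = TRUE)]
      if (any(complete %in% pm_full)) p_cnt <- p_cnt + 1L
      pw <- trimws(strsplit(win$pathways[i], ";", fixed = TRUE)[[1]])
      if (cfg$sm_pathway_id %in% pw) s_cnt <- s_cnt + 1L
    }
    res$n_P[a] <- p_cnt
    res$n_S[a] <- s_cnt
  }
  res
}
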