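# Builders shared across the test files. Everything is generated in code;
# the only on-disk fixtures are the transcribed B. subtilis neighborhoods
# under extdata.

ext_file <- function(f) {
  path <- system.file("extdata", f, package = "smrecruit")
  if (!nzchar(path)) stop("fixture not found: ", f)
  path
}

load_pm_fixture_keys <- function() {
  v <- readLines(ext_file("pm_reference_ecs_transcribed.txt"), warn = FALSE)
  v[nzchar(v) & !startsWith(v, "#")]
}

# a filtered catalog from a vector of EC strings (possibly "" or "a;b")
make_catalog <- function(ecs, role = "sm", collection = "C1",
                         lengths = 300, prefix = "g") {
  n <- length(ecs)
  cat <- as_enzyme_catalog(
    tibble::tibble(
      gene_id = paste0(prefix, seq_len(n)),
      collection_id = rep_len(collection, n),
      species_tax = "tax",
      ec = ecs,
      length = rep_len(lengths, n),
      product = "enzyme"
    ),
    role = role
  )
  apply_inclusion_filters(cat)
}

# build a function_hit_map through the real ingestion path from a hit design:
# a tibble with columns sm_ec, pm_ec, evalue (one row per intended kept hit)
make_map <- function(design, level = "full") {
  sm_ecs <- unique(design$sm_ec)
  sm <- make_catalog(sm_ecs, role = "sm", prefix = "q")
  pm <- make_catalog(design$pm_ec, role = "pm", prefix = "s")
  hits <- tibble::tibble(
    query_id = paste0("q", match(design$sm_ec, sm_ecs)),
    subject_id = paste0("s", seq_len(nrow(design))),
    evalue = design$evalue,
    bitscore = 0,
    qlen = 300,
    slen = 300
  )
  kept <- filter_hits(hits)
  function_hit_map(kept, sm, pm, level = level)
}

# random hit design over a small EC pool, for property-style tests
random_design <- function(n_keys = 8, max_hits = 6) {
  pool <- c(
    "1.1.1.1", "1.2.1.3", "2.3.1.9", "2.6.1.85", "2.7.7.58",
    "3.1.3.16", "3.4.21.26", "4.1.1.48", "4.1.3.27", "4.2.1.20",
    "5.3.1.24", "5.4.4.2", "6.2.1.26", "6.3.4.19"
  )
  sm <- sample(pool, n_keys)
  rows <- lapply(sm, function(k) {
    n <- sample.int(max_hits, 1)
    tibble::tibble(
      sm_ec = k,
      pm_ec = sample(pool, n, replace = TRUE),
      evalue = 10^runif(n, -80, -21)
    )
  })
  dplyr::bind_rows(rows)
}

write_catalog_tsv <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

write_hits12 <- function(rows, path) {
  # rows: list of character vectors of length 12 (or other, for error tests)
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

hit_row <- function(q, s, evalue, bits = 100) {
  c(q, s, "50.0", "200", "40", "2", "1", "200", "1", "200", evalue, as.character(bits))
}

md5_of <- function(paths) unname(tools::md5sum(paths))
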