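toy_genome <- function(n = 30, circular_ids = FALSE) {
  tibble::tibble(
    replicon_id = "chr",
    ordinal = seq_len(n),
    gene_id = sprintf("g%02d", seq_len(n)),
    strand = "+",
    product = "p",
    ec = "",
    pathways = ""
  )
}

test_that("neighborhood windows honor half-width, truncation and circular wrap", {
  g <- toy_genome()
  nh <- extract_neighborhood(g, "g15", k = 10)
  expect_equal(nrow(nh), 21)
  expect_equal(range(nh$offset), c(-10, 10))
  expect_equal(nh$gene_id[nh$offset == 0], "g15")

  left <- extract_neighborhood(g, "g01", k = 10)
  expect_equal(nrow(left), 11)
  expect_equal(min(left$offset), 0)

  wrap <- extract_neighborhood(g, "g01", k = 2, circular = TRUE)
  expect_equal(wrap$gene_id, c("g29", "g30", "g01", "g02", "g03"))
  expect_equal(wrap$offset, -2:2)

  expect_error(extract_neighborhood(g, "nope"), "not found")
})

test_that("P and S labels follow the reference key sets and pathway membership", {
  genome <- read_genome_table(ext_file("pabB_neighborhood_transcribed.tsv"))
  pm_keys <- load_pm_fixture_keys()
  nh <- assign_labels(
    extract_neighborhood(genome, "bsu:BSU00740", k = 10),
    pm_keys = pm_keys, sm_pathway_id = "bsu01110"
  )
  expect_true(nh$label_P[nh$gene_id == "bsu:BSU00740"]) # pabB, 2.6.1.85
  expect_true(all(nh[nh$gene_id == "bsu:BSU00680", c("label_P", "label_S")])) # hprT
  expect_false(any(unlist(nh[nh$gene_id == "bsu:BSU00650", c("label_P", "label_S")]))) # no EC
  # an EC wildcarded at full level never earns a P
  expect_false(nh$label_P[nh$gene_id == "bsu:BSU00810"]) # dusB 1.-.-.-
  expect_false(nh$label_P[nh$gene_id == "bsu:BSU00690"]) # ftsH 3.4.24.-
})

test_that("label assignment is a pure per-gene function of ECs and pathways", {
  genome <- read_genome_table(ext_file("trpE_neighborhood_transcribed.tsv"))
  pm_keys <- load_pm_fixture_keys()
  nh <- extract_neighborhood(genome, "bsu:BSU22680", k = 10)
  labeled <- assign_labels(nh, pm_keys, sm_pathway_id = "bsu01110")
  perm <- sample.int(nrow(nh))
  labeled_perm <- assign_labels(nh[perm, ], pm_keys, sm_pathway_id = "bsu01110")
  expect_equal(labeled_perm$label_P, labeled$label_P[perm])
  expect_equal(labeled_perm$label_S, labeled$label_S[perm])
})

test_that("the transcribed pabB and trpE neighborhoods reproduce the printed tallies", {
  pm_keys <- load_pm_fixture_keys()
  pab <- assign_labels(
    extract_neighborhood(
      read_genome_table(ext_file("pabB_neighborhood_transcribed.tsv")),
      "bsu:BSU00740",
      k = 10
    ),
    pm_keys,
    sm_pathway_id = "bsu01110"
  )
  expect_equal(summarize_labels(pab), tibble::tibble(n_P = 13L, n_S = 2L))

  trp <- assign_labels(
    extract_neighborhood(
      read_genome_table(ext_file("trpE_neighborhood_transcribed.tsv")),
      "bsu:BSU22680",
      k = 10
    ),
    pm_keys,
    sm_pathway_id = "bsu01110"
  )
  expect_equal(summarize_labels(trp), tibble::tibble(n_P = 17L, n_S = 16L))
})

test_that("pathway summaries count outer and inner windows with the anchor included", {
  g <- toy_genome(11)
  g$pathways[c(3, 4, 6)] <- "X" # offsets -2, -1, +1 around g05
  nh <- extract_neighborhood(g, "g05", k = 4)
  pw <- summarize_pathways(nh, k_inner = 2)
  expect_equal(pw$n_outer, 3)
  expect_equal(pw$n_inner, 3)

  g2 <- toy_genome(20)
  g2$pathways[12] <- "Y" # offset +7 from g05
  nh2 <- extract_neighborhood(g2, "g05", k = 10)
  pw2 <- summarize_pathways(nh2, k_inner = 2)
  expect_equal(pw2[pw2$pathway_id == "Y", ]$n_outer, 1)
  expect_equal(pw2[pw2$pathway_id == "Y", ]$n_inner, 0)
})

test_that("the pabB fixture reproduces the printed folate pathway row", {
  genome <- read_genome_table(ext_file("pabB_neighborhood_transcribed.tsv"))
  nh <- assign_labels(
    extract_neighborhood(genome, "bsu:BSU00740", k = 10),
    load_pm_fixture_keys(),
    sm_pathway_id = "bsu01110"
  )
  pw <- summarize_pathways(nh,
    k_inner = 2,
    pathway_map = read_pathway_map(ext_file("bsu_pathway_map_transcribed.tsv"))
  )
  folate <- pw[pw$pathway_id == "bsu00790", ]
  expect_equal(folate$n_outer, 6)
  expect_equal(folate$n_inner, 3)
  expect_equal(folate$pathway_name, "Folate biosynthesis")
  expect_equal(pw$n_outer[1], max(pw$n_outer)) # sorted by n_outer desc
  expect_true(all(pw$n_inner <= pw$n_outer))

  trp_nh <- extract_neighborhood(
    read_genome_table(ext_file("trpE_neighborhood_transcribed.tsv")),
    "bsu:BSU22680",
    k = 10
  )
  trp_pw <- summarize_pathways(trp_nh, k_inner = 2)
  expect_equal(unlist(trp_pw[trp_pw$pathway_id == "bsu01110", 1:2]),
    c(n_outer = 16L, n_inner = 5L)
  )
  expect_equal(unlist(trp_pw[trp_pw$pathway_id == "bsu00400", 1:2]),
    c(n_outer = 12L, n_inner = 5L)
  )
})

test_that("HTML reports render deterministically with hyperlinks per gene", {
  genome <- read_genome_table(ext_file("pabB_neighborhood_transcribed.tsv"))
  nh <- assign_labels(
    extract_neighborhood(genome, "bsu:BSU00740", k = 10),
    load_pm_fixture_keys(),
    sm_pathway_id = "bsu01110"
  )
  pw <- summarize_pathways(nh, k_inner = 2)
  entry <- report_entry(
    "BGC000309; SM* bsu:BSU31990 Isochorismate synthase DhbC (EC 5.4.4.2)",
    "PM bsu:BSU00740 PabB", 5e-26, nh, pw
  )
  html1 <- render_report("BGC000309", list(entry))
  html2 <- render_report("BGC000309", list(entry))
  expect_identical(html1, html2)
  expect_match(html1, "www_bget\\?bsu:BSU00740")
  expect_match(html1, "E-value 5e-26")
  expect_equal(length(gregexpr("<table", html1)[[1]]), 1)

  empty <- render_report("BGC_X", list())
  expect_match(empty, "No putative PM homologs")
  expect_error(
    render_report("B", list(entry), link_template = "https://x/"),
    "placeholder"
  )

  out <- withr::local_tempfile(fileext = ".html")
  render_report("BGC000309", list(entry), path = out)
  render_report("BGC000309", list(entry), path = paste0(out, "2"))
  expect_equal(md5_of(out), md5_of(paste0(out, "2")))
})
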