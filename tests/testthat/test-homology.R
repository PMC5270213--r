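test_that("hit tables parse the 12-column dialect and reject malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits12(list(
    c("# a comment line"),
    hit_row("q1", "s1", "5e-26"),
    hit_row("q2", "s2", "1e-30")
  ), path)
  hits <- read_hit_table(path)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$evalue[1], 5e-26)
  expect_equal(hits$query_id, c("q1", "q2"))

  write_hits12(list(hit_row("q1", "s1", "5e-26")[1:11]), path)
  expect_error(read_hit_table(path), "wrong column count.*1")

  write_hits12(list(hit_row("q1", "s1", "abc")), path)
  expect_error(read_hit_table(path), "non-numeric 'evalue'")

  write_hits12(list(c(hit_row("q1", "s1", "5e-26"), "400", "410")), path)
  ext <- read_hit_table(path, dialect = "std12_lens")
  expect_equal(ext$qlen, 400)
  expect_equal(ext$slen, 410)
})

test_that("E-value and length filters are boundary-inclusive with the query as denominator", {
  hits <- tibble::tibble(
    query_id = c("q", "q", "q", "q", "q"),
    subject_id = c("keep", "at_cutoff", "too_weak", "len_edge", "len_over"),
    evalue = c(5e-26, 1e-20, 1e-19, 1e-30, 1e-30),
    bitscore = 0,
    qlen = 100,
    slen = c(100, 100, 100, 130, 131)
  )
  kept <- filter_hits(hits)
  expect_setequal(kept$subject_id, c("keep", "at_cutoff", "len_edge"))
  rej <- hit_rejections(kept)
  expect_equal(rej$reason[rej$subject_id == "too_weak"], "evalue")
  expect_equal(rej$reason[rej$subject_id == "len_over"], "length")
})

test_that("self-hits are removed and multi-HSP pairs collapse to the best row", {
  hits <- tibble::tibble(
    query_id = c("g1", "q", "q"),
    subject_id = c("g1", "s", "s"),
    evalue = c(1e-80, 1e-40, 1e-60),
    bitscore = c(100, 50, 80),
    qlen = 100, slen = 100
  )
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$evalue, 1e-60)
  expect_equal(hit_rejections(kept)$reason, "self_hit")
  with_self <- filter_hits(hits, remove_self_hits = FALSE)
  expect_equal(nrow(with_self), 2)
})

test_that("lengths resolve from catalogs when the table lacks them", {
  qcat <- make_catalog("5.4.4.2", role = "sm", lengths = 100, prefix = "q")
  scat <- make_catalog(c("2.6.1.85", "4.1.3.27"),
    role = "pm",
    lengths = c(120, 200), prefix = "s"
  )
  hits <- tibble::tibble(
    query_id = "q1", subject_id = c("s1", "s2"),
    evalue = 1e-30, bitscore = 0
  )
  kept <- filter_hits(hits, qcat, scat)
  expect_equal(kept$subject_id, "s1") # 200 vs 100 violates the 30% rule
  expect_error(
    filter_hits(hits[1, ], qcat, NULL),
    "no subject catalog"
  )
  expect_error(
    filter_hits(tibble::tibble(
      query_id = "ghost", subject_id = "s1",
      evalue = 1e-30, bitscore = 0
    ), qcat, scat),
    "unresolvable query"
  )
})

test_that("relaxing the cutoff or tolerance never removes a kept hit", {
  set.seed(31)
  n <- 200
  hits <- tibble::tibble(
    query_id = paste0("q", sample.int(20, n, TRUE)),
    subject_id = paste0("s", seq_len(n)),
    evalue = 10^runif(n, -60, -5),
    bitscore = 0,
    qlen = 300,
    slen = round(300 * runif(n, 0.5, 1.5))
  )
  strict <- filter_hits(hits, evalue_cutoff = 1e-20)
  relaxed <- filter_hits(hits, evalue_cutoff = 1e-10)
  key <- function(h) paste(h$query_id, h$subject_id)
  expect_true(all(key(strict) %in% key(relaxed)))
  tol_wide <- filter_hits(hits, evalue_cutoff = 1e-20, length_tolerance = 0.45)
  expect_true(all(key(strict) %in% key(tol_wide)))

  # order independence: permuting rows yields the identical kept set
  perm <- filter_hits(hits[sample.int(n), ], evalue_cutoff = 1e-20)
  expect_equal(
    tibble::as_tibble(perm),
    tibble::as_tibble(strict)
  )
})

test_that("the function map pools hits per SM function and conserves them", {
  design <- tibble::tibble(
    sm_ec = c("5.4.4.2", "5.4.4.2"),
    pm_ec = c("2.6.1.85", "4.1.3.27"),
    evalue = c(5e-26, 3e-21)
  )
  map <- make_map(design)
  expect_equal(nrow(map), 2)
  expect_equal(unique(map$sm_key), "5.4.4.2")
  expect_setequal(map$pm_key, c("2.6.1.85", "4.1.3.27"))
  expect_false(any(map$same))

  # two query records sharing one EC pool into one function entry
  sm <- make_catalog(c("4.2.1.20", "4.2.1.20"), role = "sm", prefix = "q")
  pm <- make_catalog("4.2.1.20", role = "pm", prefix = "s")
  hits <- tibble::tibble(
    query_id = c("q1", "q2"), subject_id = "s1",
    evalue = 1e-40, bitscore = 0, qlen = 300, slen = 300
  )
  map2 <- function_hit_map(filter_hits(hits), sm, pm, "full")
  expect_equal(nrow(map2), 2)
  expect_equal(unique(map2$sm_key), "4.2.1.20")

  empty <- function_hit_map(filter_hits(hits[0, ]), sm, pm, "full")
  expect_equal(nrow(empty), 0)
})

test_that("hits incomplete at a level drop out of that level's map only", {
  sm <- make_catalog(c("5.4.4.2", "1.-.-.-"), role = "sm", prefix = "q")
  pm <- make_catalog(c("2.6.1.85", "1.1.1.1"), role = "pm", prefix = "s")
  hits <- tibble::tibble(
    query_id = c("q1", "q2"), subject_id = c("s1", "s2"),
    evalue = 1e-40, bitscore = 0, qlen = 300, slen = 300
  )
  kept <- filter_hits(hits)
  expect_equal(nrow(function_hit_map(kept, sm, pm, "full")), 1)
  expect_equal(nrow(function_hit_map(kept, sm, pm, "class")), 2)
})
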