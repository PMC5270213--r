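ics_design <- function() {
  tibble::tibble(
    sm_ec = c("5.4.4.2", "5.4.4.2"),
    pm_ec = c("2.6.1.85", "4.1.3.27"),
    evalue = c(5e-26, 3e-21)
  )
}

test_that("functions classify as ALL_SAME, MIXED or ALL_DIFF from their homolog makeup", {
  cls <- classify_functions(make_map(ics_design()))
  expect_equal(as.character(cls$category), "ALL_DIFF")
  expect_equal(cls$n_same, 0)
  expect_equal(cls$n_hits, 2)

  mono <- make_map(tibble::tibble(
    sm_ec = "4.2.1.20", pm_ec = "4.2.1.20", evalue = 1e-40
  ))
  expect_equal(as.character(classify_functions(mono)$category), "ALL_SAME")

  mixed <- make_map(tibble::tibble(
    sm_ec = rep("2.7.7.58", 3),
    pm_ec = c("2.7.7.58", "2.7.7.58", "6.2.1.26"),
    evalue = 1e-40
  ))
  c_m <- classify_functions(mixed)
  expect_equal(as.character(c_m$category), "MIXED")
  expect_equal(c_m$n_same, 2)
  expect_equal(c_m$n_hits, 3)
})

test_that("classification at class level is never more different than at full level", {
  for (seed in 1:4) {
    set.seed(seed)
    design <- random_design()
    full <- classify_functions(make_map(design, "full"))
    class_lvl <- classify_functions(make_map(design, "class"))
    # same at full implies same at class: per-key n_same can only grow
    merged <- dplyr::inner_join(
      dplyr::mutate(tibble::as_tibble(full), ckey = ec_key(.data$key, "class")),
      tibble::as_tibble(class_lvl),
      by = c(ckey = "key"), suffix = c("_full", "_class")
    ) |>
      dplyr::group_by(.data$ckey) |>
      dplyr::summarise(
        same_full = sum(.data$n_same_full),
        same_class = dplyr::first(.data$n_same_class)
      )
    expect_true(all(merged$same_class >= merged$same_full))
  }
})

test_that("summaries reproduce printed-arithmetic fractions under an explicit denominator", {
  # 48 monofunctional, 45 multifunctional, 3 fully changed subdivisions,
  # quoted against 123 SM subdivisions in total
  design <- dplyr::bind_rows(
    tibble::tibble(
      sm_ec = sprintf("1.%d.1.1", 1:48),
      pm_ec = sprintf("1.%d.1.1", 1:48), evalue = 1e-30
    ),
    tibble::tibble(
      sm_ec = rep(sprintf("2.%d.1.1", 1:45), each = 2),
      pm_ec = as.vector(rbind(sprintf("2.%d.1.1", 1:45), "6.1.1.1")),
      evalue = 1e-30
    ),
    tibble::tibble(
      sm_ec = sprintf("3.%d.1.1", 1:3),
      pm_ec = "6.1.1.1", evalue = 1e-30
    )
  )
  cls <- classify_functions(make_map(design, "subdivision"))
  expect_equal(nrow(cls), 96)
  s <- summarize_classification(cls, n_total = 123)
  frac <- setNames(s$fraction, as.character(s$category))
  expect_equal(round(frac[["ALL_SAME"]]), 39)
  expect_equal(round(frac[["MIXED"]]), 37)
  expect_equal(frac[["ALL_SAME"]], 100 * 48 / 123)
  expect_equal(frac[["ALL_DIFF"]], 100 * 3 / 123)

  # default denominator: fractions cover the classified keys and sum to 100
  s0 <- summarize_classification(cls)
  expect_equal(sum(s0$fraction), 100)
  expect_equal(sum(s0$n), attr(s0, "n_keys"))

  single <- summarize_classification(
    classify_functions(make_map(tibble::tibble(
      sm_ec = "1.1.1.1", pm_ec = "1.1.1.1", evalue = 1e-30
    )))
  )
  expect_equal(single$fraction, c(100, 0, 0))

  expect_error(
    summarize_classification(cls[0, ]),
    "no classifications"
  )
})

test_that("glance and tidy expose flexibility summaries in broom shape", {
  cls <- classify_functions(make_map(ics_design()))
  s <- summarize_classification(cls)
  expect_named(tidy(s), c("category", "n", "fraction"))
  g <- glance(s)
  expect_equal(g$n_keys, 1)
  expect_equal(g$frac_all_diff, 100)
})

test_that("functional conservation is the hit-weighted same-function fraction", {
  all_same <- make_map(tibble::tibble(
    sm_ec = rep(c("1.1.1.1", "4.2.1.20"), each = 2),
    pm_ec = rep(c("1.1.1.1", "4.2.1.20"), each = 2),
    evalue = 1e-40
  ))
  expect_equal(functional_conservation(all_same)$fc, c(1, 1))

  three_of_four <- make_map(tibble::tibble(
    sm_ec = rep("4.2.1.20", 4),
    pm_ec = c("4.2.1.20", "4.2.1.20", "4.2.1.20", "2.6.1.85"),
    evalue = 1e-40
  ))
  expect_equal(functional_conservation(three_of_four)$fc, 0.75)
})

test_that("fc matches a brute-force recount on random maps", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    design <- random_design()
    for (level in c("class", "subdivision", "full")) {
      fc <- functional_conservation(make_map(design, level))
      # independent recount via plain string prefixes
      depth <- match(level, ec_levels())
      prefix <- function(e) {
        vapply(
          strsplit(e, ".", fixed = TRUE),
          function(p) paste(p[seq_len(depth)], collapse = "."), character(1)
        )
      }
      sk <- prefix(design$sm_ec)
      pk <- prefix(design$pm_ec)
      for (i in seq_len(nrow(fc))) {
        sel <- sk == fc$key[i]
        expect_equal(fc$fc[i], sum(pk[sel] == fc$key[i]) / sum(sel))
      }
      # partition identity: categories cover every key with >= 1 hit
      cls <- classify_functions(make_map(design, level))
      expect_equal(sum(table(cls$category)), length(unique(sk)))
    }
  }
})

test_that("recruitment fractions bound the recruited share of SM functions", {
  expect_equal(recruitment_fraction(331, 600), 100 * 331 / 600)
  expect_gte(recruitment_fraction(331, 600), 55)
  expect_equal(recruitment_fraction(0, 10), 0)
  expect_equal(recruitment_fraction(10, 10), 100)
  expect_error(recruitment_fraction(1, 0))
  rs <- recruitment_summary(331, 600)
  expect_equal(rs$n_exclusive, 269)
})

test_that("the EC hits-counts table reports TOT/SAME/DIFF per function", {
  counts <- ec_hits_counts(make_map(ics_design()))
  expect_equal(counts$TOT, 2)
  expect_equal(counts$SAME, 0)
  expect_equal(counts$DIFF, 2)
})
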