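test_that("frequency spectra count records and normalize to percent", {
  cat <- make_catalog(c("2.3.1.1", "2.3.1.9", "2.7.7.1", "4.2.1.20"))
  f <- ec_frequencies(cat, "class")
  expect_equal(f$key, c("2", "4"))
  expect_equal(f$freq, c(75, 25))
  expect_equal(f$n, c(3L, 1L))

  single <- ec_frequencies(make_catalog("5.4.4.2"), "subdivision")
  expect_equal(single$freq, 100)
  expect_equal(single$key, "5.4.4")

  empty <- ec_frequencies(make_catalog(character()), "class")
  expect_equal(nrow(empty), 0)
})

test_that("records incomplete at a level drop out of that level's denominator", {
  cat <- make_catalog(c("1.-.-.-", "1.1.1.1", "2.3.1.9"))
  f_class <- ec_frequencies(cat, "class")
  expect_equal(sum(f_class$n), 3) # wildcard class is still concrete
  f_full <- ec_frequencies(cat, "full")
  expect_equal(sum(f_full$n), 2)
  expect_equal(attr(f_full, "n_dropped"), 1)
})

test_that("spectra are normalized and scale-invariant on random catalogs", {
  for (seed in 1:5) {
    set.seed(seed)
    ecs <- sprintf(
      "%d.%d.%d.%d", sample.int(6, 80, TRUE), sample.int(9, 80, TRUE),
      sample.int(9, 80, TRUE), sample.int(50, 80, TRUE)
    )
    cat <- make_catalog(ecs)
    doubled <- make_catalog(c(ecs, ecs))
    for (level in ec_levels()) {
      f <- ec_frequencies(cat, level)
      expect_lt(abs(sum(f$freq) - 100), 1e-6)
      expect_true(all(f$freq >= 0))
      f2 <- ec_frequencies(doubled, level)
      expect_equal(f2$key, f$key)
      expect_equal(f2$freq, f$freq)
    }
  }
})

test_that("overrepresentation ratios divide SM by PM frequencies with absence handling", {
  sm <- ec_frequencies(make_catalog(c("1.1.1.1", "2.3.1.9")), "class")
  pm <- ec_frequencies(make_catalog(c("1.1.1.1", "2.3.1.9")), "class")
  ov <- overrep_ratios(sm, pm)
  expect_equal(ov$ratio, c(1, 1))

  sm2 <- ec_frequencies(make_catalog(c("1.1.1.1", rep("2.3.1.9", 9))), "class")
  pm2 <- ec_frequencies(make_catalog(c(rep("1.1.1.1", 19), "2.3.1.9")), "class")
  ov2 <- overrep_ratios(sm2, pm2)
  # f_sm(2) = 90, f_pm(2) = 5 -> ratio 18
  expect_equal(ov2$ratio[ov2$key == "2"], 18)

  sm3 <- ec_frequencies(make_catalog(c("1.1.1.1", "3.1.3.16")), "class")
  pm3 <- ec_frequencies(make_catalog(c("1.1.1.1", "2.3.1.9")), "class")
  ov3 <- overrep_ratios(sm3, pm3)
  expect_true(ov3$absent_in_pm[ov3$key == "3"])
  expect_true(is.na(ov3$ratio[ov3$key == "3"]))
  expect_equal(ov3$ratio[ov3$key == "2"], 0)

  expect_error(
    overrep_ratios(sm, ec_frequencies(make_catalog("1.1.1.1"), "full")),
    "different levels"
  )
})

test_that("overrepresentation is reciprocal between the two directions", {
  for (seed in 1:3) {
    set.seed(seed)
    mk <- function() {
      make_catalog(sprintf(
        "%d.%d.1.1", sample.int(6, 60, TRUE),
        sample.int(4, 60, TRUE)
      ))
    }
    a <- ec_frequencies(mk(), "subclass")
    b <- ec_frequencies(mk(), "subclass")
    fwd <- overrep_ratios(a, b)
    rev <- overrep_ratios(b, a)
    both <- intersect(
      fwd$key[!is.na(fwd$ratio) & fwd$ratio > 0],
      rev$key[!is.na(rev$ratio) & rev$ratio > 0]
    )
    prod <- fwd$ratio[match(both, fwd$key)] * rev$ratio[match(both, rev$key)]
    expect_equal(prod, rep(1, length(both)))
  }
})

test_that("shared and exclusive function sets partition the key union", {
  sm <- make_catalog(c("1.1.1.1", "2.3.1.9"))
  pm <- make_catalog(c("2.3.1.9", "4.2.1.20"))
  sets <- shared_exclusive_functions(sm, pm, "full")
  expect_equal(sets$shared, "2.3.1.9")
  expect_equal(sets$sm_only, "1.1.1.1")
  expect_equal(sets$pm_only, "4.2.1.20")

  same <- shared_exclusive_functions(sm, sm, "full")
  expect_length(same$sm_only, 0)
  expect_length(same$pm_only, 0)

  all_keys <- c(sets$shared, sets$sm_only, sets$pm_only)
  expect_equal(anyDuplicated(all_keys), 0)
  expect_setequal(all_keys, union(unique(sm$ec), unique(pm$ec)))
})

test_that("frequency correlation squares Pearson's r under both pairing policies", {
  a <- ec_frequencies(make_catalog(c("1.1.1.1", rep("2.3.1.9", 2), rep("4.2.1.20", 3))), "class")
  b <- ec_frequencies(make_catalog(c(rep("1.1.1.1", 3), rep("2.3.1.9", 2), "4.2.1.20")), "class")
  # frequencies (1,2,3)/6 vs (3,2,1)/6: perfect anti-correlation squares to 1
  expect_equal(frequency_correlation(a, b), 1.0)
  expect_equal(frequency_correlation(a, a), 1.0)

  # independent closed-form Pearson oracle on a non-trivial pairing
  r2_manual <- function(x, y) {
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
    (num / den)^2
  }
  set.seed(21)
  c1 <- make_catalog(sprintf("%d.1.1.1", sample.int(6, 50, TRUE)))
  c2 <- make_catalog(sprintf("%d.1.1.1", sample.int(5, 50, TRUE)))
  fa <- ec_frequencies(c1, "class")
  fb <- ec_frequencies(c2, "class")
  keys_u <- union(fa$key, fb$key)
  xa <- ifelse(keys_u %in% fa$key, fa$freq[match(keys_u, fa$key)], 0)
  xb <- ifelse(keys_u %in% fb$key, fb$freq[match(keys_u, fb$key)], 0)
  expect_equal(frequency_correlation(fa, fb, "union_zero_fill"), r2_manual(xa, xb))
  keys_i <- intersect(fa$key, fb$key)
  expect_equal(
    frequency_correlation(fa, fb, "intersection"),
    r2_manual(fa$freq[match(keys_i, fa$key)], fb$freq[match(keys_i, fb$key)])
  )
})

test_that("degenerate correlation inputs are rejected", {
  two_keys <- ec_frequencies(make_catalog(c("1.1.1.1", "2.3.1.9")), "class")
  expect_error(frequency_correlation(two_keys, two_keys), "fewer than 3")
  flat <- ec_frequencies(
    make_catalog(c("1.1.1.1", "2.3.1.9", "4.2.1.20")), "class"
  )
  expect_error(frequency_correlation(flat, flat), "zero variance")
})
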