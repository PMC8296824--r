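fixture_records <- function() {
  read_action_level_table(system.file("extdata",
                                      "action_levels_illustrative.csv",
                                      package = "cgpdnet"))
}
fixture_tolerances <- function() {
  read_reference_tolerances(system.file(
    "extdata", "reference_tolerances_illustrative.csv",
    package = "cgpdnet"))
}

test_that("fixture statistics reproduce the anchored regulatory spans", {
  st <- pesticide_stats(fixture_records(), fixture_tolerances())
  row <- function(p) st[st$pesticide == p, ]
  expect_equal(row("azoxystrobin")$fold_range, 4000)   # 0.01 to 40 ppm
  expect_equal(row("chlorantraniliprole")$fold_range, 4000)
  expect_equal(row("dimethomorph")$fold_range, 600)    # 0.1 to 60 ppm
  expect_equal(row("dimethomorph")$n_jurisdictions, 5L)
  ## ethephon: zero tolerance uses the LOQ in the denominator only
  e <- row("ethephon")
  expect_equal(e$min_level, 0)
  expect_equal(e$median_level, 0.002)
  expect_equal(e$fold_range, 1 / 0.002)
  expect_equal(e$median_to_reference_ratio, 1)
})

test_that("median and fold-range conventions", {
  mk <- function(levels, loq = NA_real_) {
    data.frame(jurisdiction = sprintf("J%02d", seq_along(levels)),
               pesticide = "x", class = "other", product_type = "any",
               action_level = levels, loq = loq,
               zero_tolerance = levels == 0, stringsAsFactors = FALSE)
  }
  ## single record
  s1 <- pesticide_stats(mk(5))
  expect_equal(c(s1$min_level, s1$median_level, s1$max_level), c(5, 5, 5))
  expect_equal(s1$fold_range, 1)
  ## odd-count median
  expect_equal(pesticide_stats(mk(c(0.1, 1, 60)))$median_level, 1)
  ## even-count median = mean of the middle two
  expect_equal(pesticide_stats(mk(c(1, 2, 3, 10)))$median_level, 2.5)
  ## all-zero with no LOQ: fold-range undefined, min still 0
  s0 <- pesticide_stats(mk(c(0, 0)))
  expect_true(is.na(s0$fold_range))
  expect_equal(s0$min_level, 0)
  ## zero-tolerance row without LOQ is excluded from the denominator
  sz <- pesticide_stats(mk(c(0, 1, 10)))
  expect_equal(sz$fold_range, 10)
})

test_that("statistics are permutation- and duplication-invariant", {
  rec <- fixture_records()
  base <- pesticide_stats(rec, fixture_tolerances())
  set.seed(3)
  perm <- pesticide_stats(rec[sample(nrow(rec)), ], fixture_tolerances())
  expect_equal(perm, base)
  ## exact duplicate records collapse before statistics
  dup <- pesticide_stats(rbind(rec, rec[3, ]), fixture_tolerances())
  expect_equal(dup$median_level, base$median_level)
  expect_equal(dup$fold_range, base$fold_range)
  expect_equal(dup$n_records, base$n_records)
})

test_that("fold-range is invariant under unit-preserving rescaling", {
  rec <- fixture_records()
  scaled <- rec
  scaled$action_level <- scaled$action_level * 1000
  scaled$loq <- scaled$loq * 1000
  scaled$zero_tolerance <- scaled$action_level == 0
  a <- pesticide_stats(rec)
  b <- pesticide_stats(scaled)
  expect_equal(b$fold_range, a$fold_range)
  expect_equal(b$median_level, a$median_level * 1000)
})

test_that("regulation breadth counts jurisdictions once per pesticide", {
  rec <- fixture_records()
  ## dual product listings must not double-count a jurisdiction
  extra <- rec[rec$pesticide == "abamectin", ][1, ]
  extra$product_type <- "inhalable"
  rb <- regulation_breadth(rbind(rec, extra))
  expect_equal(rb$breadth$n_jurisdictions[rb$breadth$pesticide ==
                                          "abamectin"], 5L)
  expect_equal(rb$breadth$n_jurisdictions[rb$breadth$pesticide ==
                                          "azoxystrobin"], 17L)
  ## histogram bins are integers 1..J and column sums count pesticides
  J <- length(unique(rec$jurisdiction))
  expect_setequal(unique(rb$histogram$n_jurisdictions), seq_len(J))
  expect_equal(sum(rb$histogram$n_pesticides), nrow(rb$breadth))
})

test_that("top variation sorts by fold-range with lexicographic ties", {
  st <- pesticide_stats(fixture_records(), fixture_tolerances())
  top <- top_variation(st, 3)
  ## the two 4000-fold pesticides rank first, alphabetically
  expect_equal(top$pesticide[1:2], c("azoxystrobin", "chlorantraniliprole"))
  expect_equal(top$pesticide[3], "dimethomorph")
  ## k larger than the table returns the whole defined-fold table
  expect_equal(nrow(top_variation(st, 100)), sum(!is.na(st$fold_range)))
  ## undefined fold-ranges are excluded with a note
  zz <- data.frame(jurisdiction = "J01", pesticide = "zz", class = "other",
                   product_type = "any", action_level = 0, loq = NA_real_,
                   zero_tolerance = TRUE, stringsAsFactors = FALSE)
  st2 <- pesticide_stats(rbind(fixture_records(), zz))
  expect_message(t2 <- top_variation(st2, 100), "undefined")
  expect_false("zz" %in% t2$pesticide)
})

test_that("barbell table pairs tolerances with medians", {
  st <- pesticide_stats(fixture_records(), fixture_tolerances())
  bb <- barbell_table(st, reported = data.frame(pesticide = "ethephon",
                                                reported_ppm = 0.5))
  expect_setequal(bb$pesticide, c("ethephon", "azoxystrobin",
                                  "dimethomorph"))
  e <- bb[bb$pesticide == "ethephon", ]
  expect_equal(e$lowest_tolerance, 0.002)
  expect_equal(e$median_level, 0.002)
  expect_equal(e$reported_ppm, 0.5)     # identity join
  expect_false("abamectin" %in% bb$pesticide)  # no tolerance, omitted
})

test_that("mean fold above reference: arithmetic, geometric, errors", {
  st <- data.frame(pesticide = c("a", "b"), class = "other",
                   n_records = 1L, n_jurisdictions = 1L,
                   min_level = c(2, 8), median_level = c(2, 8),
                   max_level = c(2, 8), fold_range = 1,
                   reference_tolerance = c(1, 1),
                   median_to_reference_ratio = c(2, 8),
                   stringsAsFactors = FALSE)
  expect_equal(mean_fold_above_reference(st)$mean_ratio, 5)
  expect_equal(mean_fold_above_reference(st, method = "geometric")$mean_ratio,
               4)
  st$reference_tolerance[2] <- NA
  expect_error(mean_fold_above_reference(st, subset = c("a", "b")), "b")
  expect_error(mean_fold_above_reference(st, subset = "zz"), "zz")
})

test_that("product-type filtering separates dual-listed records", {
  rec <- rbind(
    data.frame(jurisdiction = "CA", pesticide = "x", class = "other",
               product_type = "inhalable", action_level = 0.1,
               loq = NA_real_, zero_tolerance = FALSE),
    data.frame(jurisdiction = "CA", pesticide = "x", class = "other",
               product_type = "non-inhalable", action_level = 3,
               loq = NA_real_, zero_tolerance = FALSE))
  pooled <- pesticide_stats(rec)
  expect_equal(pooled$fold_range, 30)
  inh <- pesticide_stats(rec, product_filter = "inhalable")
  expect_equal(inh$max_level, 0.1)
  expect_error(pesticide_stats(rec, product_filter = "extract"),
               "no action-level records")
})
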