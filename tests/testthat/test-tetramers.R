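test_that("a minimal complete instance yields exactly one tetramer", {
  ts <- build_tetramers(minimal_instance(), DIS)
  expect_equal(nrow(ts$tetramers), 1L)
  expect_equal(ts$tetramers$chemical, "MESH:C1")
  expect_equal(ts$tetramers$gene, "GENE:G1")
  expect_equal(ts$tetramers$phenotype, "GO:0000001")
  expect_equal(ts$tetramers$disease, DIS)
})

test_that("removing any one evidence line voids the tetramer", {
  for (nm in names(minimal_instance())) {
    ints <- minimal_instance()
    ints[[nm]] <- ints[[nm]][0, , drop = FALSE]
    ts <- suppressWarnings(build_tetramers(ints, DIS))
    expect_equal(nrow(ts$tetramers), 0L)
  }
})

test_that("full 2x2x2 instance matches the brute-force oracle (8 tetramers)", {
  ints <- full_2x2x2()
  ts <- build_tetramers(ints, DIS)
  expect_equal(nrow(ts$tetramers), 8L)
  expect_identical(tetramer_ids(ts), oracle_tetramers(ints))
  expect_equal(unname(distinct_entities(ts)), c(2L, 2L, 2L))
})

test_that("duplicate evidence rows collapse: counts are per quadruple", {
  ints <- minimal_instance()
  ints$chem_gene <- rbind(ints$chem_gene, ints$chem_gene)
  ints$gene_disease <- rbind(ints$gene_disease, ints$gene_disease,
                             ints$gene_disease)
  ts <- build_tetramers(ints, DIS)
  expect_equal(nrow(ts$tetramers), 1L)
})

test_that("construction matches the oracle on random instances", {
  set.seed(2024)
  for (i in 1:12) {
    ints <- random_instance(nc = sample(3:7, 1), ng = sample(3:7, 1),
                            np = sample(3:8, 1),
                            density = stats::runif(1, 0.15, 0.6))
    ts <- suppressWarnings(build_tetramers(ints, DIS))
    expect_identical(tetramer_ids(ts), oracle_tetramers(ints))
  }
})

test_that("adding records is monotone; removing a supporting pair prunes", {
  set.seed(7)
  ints <- random_instance(5, 5, 6, density = 0.4)
  ts <- suppressWarnings(build_tetramers(ints, DIS))
  ## adding a fresh chem-gene record never removes tetramers
  more <- ints
  more$chem_gene <- rbind(more$chem_gene,
                          int_records("chem-gene", "MESH:R01", "GENE:RG02"))
  ts2 <- suppressWarnings(build_tetramers(more, DIS))
  expect_true(all(tetramer_ids(ts) %in% tetramer_ids(ts2)))
  ## removing a pair supporting some tetramer removes at least that one
  if (nrow(ts$tetramers) > 0) {
    victim <- ts$tetramers[1, ]
    pruned <- ints
    keep <- !(pruned$gene_phenotype$subject_key == victim$gene &
              pruned$gene_phenotype$object_key == victim$phenotype)
    pruned$gene_phenotype <- pruned$gene_phenotype[keep, , drop = FALSE]
    ts3 <- suppressWarnings(build_tetramers(pruned, DIS))
    vid <- paste(victim$chemical, victim$gene, victim$phenotype, sep = "|")
    expect_false(vid %in% tetramer_ids(ts3))
    expect_true(all(tetramer_ids(ts3) %in% tetramer_ids(ts)))
  }
})

test_that("evidence audit: every emitted tetramer has all five raw pairs", {
  set.seed(11)
  ints <- random_instance(6, 6, 6, density = 0.35)
  ts <- suppressWarnings(build_tetramers(ints, DIS))
  has <- function(df, s, o) any(df$subject_key == s & df$object_key == o)
  for (i in seq_len(nrow(ts$tetramers))) {
    t0 <- ts$tetramers[i, ]
    expect_true(has(ints$chem_gene, t0$chemical, t0$gene))
    expect_true(has(ints$chem_phenotype, t0$chemical, t0$phenotype))
    expect_true(has(ints$gene_phenotype, t0$gene, t0$phenotype))
    expect_true(has(ints$chem_disease, t0$chemical, DIS))
    expect_true(has(ints$gene_disease, t0$gene, DIS))
  }
})

test_that("construction is idempotent with deterministic ordering", {
  set.seed(5)
  ints <- random_instance(6, 5, 6, density = 0.4)
  a <- suppressWarnings(build_tetramers(ints, DIS))
  ## permute input row order: output must be identical
  perm <- lapply(ints, function(df) df[sample(nrow(df)), , drop = FALSE])
  b <- suppressWarnings(build_tetramers(perm, DIS))
  expect_identical(a$tetramers, b$tetramers)
  ord <- order(sub("^[^:]+:", "", a$tetramers$chemical),
               sub("^[^:]+:", "", a$tetramers$gene),
               sub("^[^:]+:", "", a$tetramers$phenotype))
  expect_identical(ord, seq_len(nrow(a$tetramers)))
})

test_that("absent disease warns and returns an empty set", {
  expect_warning(ts <- build_tetramers(minimal_instance(), "MESH:D999999"),
                 "absent")
  expect_equal(nrow(ts$tetramers), 0L)
})

test_that("chemical scope restricts construction", {
  ints <- full_2x2x2()
  ts <- build_tetramers(ints, DIS, chemical_scope = "MESH:C1")
  expect_equal(unique(ts$tetramers$chemical), "MESH:C1")
  expect_equal(nrow(ts$tetramers), 4L)
})

test_that("per-chemical counts sum to the total and omit zero chemicals", {
  ints <- full_2x2x2()
  ts <- build_tetramers(ints, DIS)
  cnt <- tetramer_counts(ts)
  expect_equal(sum(cnt$n_tetramers), nrow(ts$tetramers))
  expect_false(any(cnt$n_tetramers == 0))
  expect_equal(tetramer_counts(build_tetramers(minimal_instance(), DIS,
                                               "MESH:NONE"))$n_tetramers,
               integer(0))
})

test_that("shared entities: identity, disjoint, and disease mismatch", {
  ints <- full_2x2x2()
  a <- build_tetramers(ints, DIS, "MESH:C1")
  b <- build_tetramers(ints, DIS, "MESH:C2")
  sh <- shared_entities(a, b)
  expect_setequal(sh$genes, c("GENE:G1", "GENE:G2"))
  self <- shared_entities(a, a)
  expect_setequal(self$genes, unique(a$tetramers$gene))

  other <- minimal_instance(chem = "MESH:C9", gene = "GENE:G9",
                            phen = "GO:0000009")
  d <- build_tetramers(other, DIS)
  expect_length(shared_entities(a, d)$genes, 0L)

  mism <- d
  mism$disease <- "MESH:D000001"
  expect_error(shared_entities(a, mism), "different disease")
})

test_that("epilepsy overlap flags panel genes case-insensitively", {
  ints <- full_2x2x2()
  ts <- build_tetramers(ints, DIS)
  ov <- epilepsy_overlap(ts, c("g1"))
  expect_equal(nrow(ov), 2L)
  expect_equal(ov$epilepsy[ov$gene == "GENE:G1"], TRUE)
  expect_equal(ov$epilepsy[ov$gene == "GENE:G2"], FALSE)
  expect_equal(ov$n_tetramers, c(4L, 4L))
  expect_equal(ov$chemicals, c("C1,C2", "C1,C2"))
  expect_error(epilepsy_overlap(ts, character()), "non-empty")
})

test_that("tetramer TSV export round-trips through the standard reader", {
  ts <- build_tetramers(full_2x2x2(), DIS)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tetramers(ts, f)
  back <- utils::read.table(f, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  expect_equal(back$chemical, ts$tetramers$chemical)
  expect_equal(back$phenotype, ts$tetramers$phenotype)
})

test_that("print and summary methods report the headline counts", {
  ts <- build_tetramers(full_2x2x2(), DIS)
  expect_output(print(ts), "tetramers: 8")
  s <- summary(ts)
  expect_equal(s$n_tetramers, 8L)
  expect_output(print(s), "8 tetramers")
})
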