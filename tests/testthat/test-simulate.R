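small_sim <- function(seed = 4, T_ins = 20, T_cab = 5, decoy = 0.5) {
  simulate_ctd_tables(n_chemicals = 8, n_cannabinoids = 2, n_genes = 14,
                      n_phenotypes = 24,
                      n_tetramers = c(insecticide = T_ins,
                                      cannabinoid = T_cab),
                      decoy_density = decoy, shared_genes = 4,
                      shared_phenotypes = 2, n_cannabinoid_genes = 6,
                      n_cannabinoid_phenotypes = 5, seed = seed)
}

test_that("planted tetramers are recovered exactly, decoys never complete", {
  sim <- simulate_ctd_tables(n_chemicals = 8, n_cannabinoids = 2,
                             n_genes = 14, n_phenotypes = 24,
                             n_tetramers = c(insecticide = 25,
                                             cannabinoid = 0),
                             decoy_density = 0.5, shared_genes = 0,
                             shared_phenotypes = 0,
                             n_cannabinoid_genes = 6,
                             n_cannabinoid_phenotypes = 5, seed = 21)
  ts <- build_tetramers(sim$interactions, sim$disease)
  gt <- sim$ground_truth
  expect_equal(nrow(ts$tetramers), 25L)
  expect_identical(
    tetramer_ids(ts),
    sort(paste(gt$tetramers$chemical, gt$tetramers$gene,
               gt$tetramers$phenotype, sep = "|")))
  ## independent oracle re-verification of completeness
  expect_identical(tetramer_ids(ts), oracle_tetramers(sim$interactions))
  ## no decoy chemical appears in any tetramer
  expect_false(any(gt$decoys$chemical %in% ts$tetramers$chemical))
})

test_that("decoy-only instance builds zero tetramers", {
  sim <- simulate_ctd_tables(n_chemicals = 4, n_cannabinoids = 1,
                             n_genes = 6, n_phenotypes = 8,
                             n_tetramers = c(insecticide = 0,
                                             cannabinoid = 0),
                             decoy_density = 1, shared_genes = 0,
                             shared_phenotypes = 0,
                             n_cannabinoid_genes = 2,
                             n_cannabinoid_phenotypes = 2, seed = 3)
  ## decoy count is tied to planted count, so force decoys directly off a
  ## tiny planted set and drop the planted chemical from scope instead
  expect_equal(sim$ground_truth$n_tetramers, 0L)
  ts <- suppressWarnings(build_tetramers(sim$interactions, sim$disease))
  expect_equal(nrow(ts$tetramers), 0L)
})

test_that("every decoy misses exactly one evidence line", {
  sim <- small_sim(seed = 8)
  dec <- sim$ground_truth$decoys
  expect_gt(nrow(dec), 0L)
  has <- function(df, s, o) any(df$subject_key == s & df$object_key == o)
  for (i in seq_len(nrow(dec))) {
    d <- dec[i, ]
    present <- c(
      "chem-gene" = has(sim$interactions$chem_gene, d$chemical, d$gene),
      "chem-phenotype" = has(sim$interactions$chem_phenotype, d$chemical,
                             d$phenotype),
      "gene-phenotype" = has(sim$interactions$gene_phenotype, d$gene,
                             d$phenotype),
      "chem-disease" = has(sim$interactions$chem_disease, d$chemical,
                           sim$disease),
      "gene-disease" = has(sim$interactions$gene_disease, d$gene,
                           sim$disease))
    expect_equal(sum(!present), 1L)
    expect_equal(names(present)[!present], d$missing_line)
  }
})

test_that("identical seeds give identical tables, different seeds differ", {
  a <- small_sim(seed = 10)
  b <- small_sim(seed = 10)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$ground_truth$tetramers, b$ground_truth$tetramers)
  c0 <- small_sim(seed = 11)
  expect_false(identical(a$ground_truth$tetramers,
                         c0$ground_truth$tetramers))
})

test_that("per-chemical quotas and shared-entity counts are exact", {
  quotas <- c(5L, 4L, 3L, 2L, 1L, 0L, 3L, 2L)
  sim <- simulate_ctd_tables(n_chemicals = 8, n_cannabinoids = 2,
                             n_genes = 14, n_phenotypes = 24,
                             quotas = quotas, decoy_density = 0.3,
                             shared_genes = 3, shared_phenotypes = 2,
                             n_cannabinoid_genes = 6,
                             n_cannabinoid_phenotypes = 5, seed = 17)
  ts <- build_tetramers(sim$interactions, sim$disease)
  cnt <- tetramer_counts(ts)
  chems <- sprintf("MESH:C%03d", 1:8)
  got <- cnt$n_tetramers[match(chems, cnt$chemical)]
  got[is.na(got)] <- 0L
  expect_equal(got, quotas)

  ins <- unique(sim$classes$chemical_key[sim$classes$label == "insecticide"])
  cab <- unique(sim$classes$chemical_key[sim$classes$label == "cannabinoid"])
  sh <- shared_entities(build_tetramers(sim$interactions, sim$disease, ins),
                        build_tetramers(sim$interactions, sim$disease, cab))
  expect_length(sh$genes, 3L)
  expect_length(sh$phenotypes, 2L)
})

test_that("infeasible quotas raise a configuration error", {
  expect_error(
    simulate_ctd_tables(n_chemicals = 3, n_cannabinoids = 1, n_genes = 3,
                        n_phenotypes = 3,
                        quotas = c(50L, 0L, 0L), decoy_density = 0,
                        shared_genes = 0, shared_phenotypes = 0,
                        n_cannabinoid_genes = 1,
                        n_cannabinoid_phenotypes = 1, seed = 1),
    "infeasible|capacity")
})

test_that("action-level construction realizes planted statistics exactly", {
  spec <- data.frame(
    pesticide = c("alpha", "beta", "gamma", "delta"),
    class = "insecticide",
    n_jurisdictions = c(17L, 12L, 1L, 9L),
    min = c(0.01, 0.01, 5, 0.002),
    max = c(40, 40, 5, 1),
    median = c(0.3, NA, NA, NA),
    zero_tolerance = c(FALSE, FALSE, FALSE, TRUE),
    loq = c(NA, NA, NA, 0.005), stringsAsFactors = FALSE)
  al <- simulate_action_levels(spec, seed = 5)
  st <- pesticide_stats(al$records)
  gt <- al$ground_truth
  m <- match(gt$pesticide, st$pesticide)
  expect_equal(st$min_level[m], gt$min)
  expect_equal(st$median_level[m], gt$median)
  expect_equal(st$max_level[m], gt$max)
  expect_equal(st$fold_range[m], gt$fold_range)
  expect_equal(st$n_jurisdictions[m], gt$n_jurisdictions)
  ## the planted 4000-fold span and the single-record degenerate case
  expect_equal(st$fold_range[st$pesticide == "alpha"], 4000)
  expect_equal(st$fold_range[st$pesticide == "gamma"], 1)
  expect_equal(st$median_level[st$pesticide == "alpha"], 0.3)
  ## planted median outside the range is a configuration error
  bad <- spec[1, ]; bad$median <- 100
  expect_error(simulate_action_levels(bad, seed = 1), "outside")
})

test_that("planted mean fold-ratio is recovered by both averaging methods", {
  spec <- data.frame(pesticide = sprintf("p%02d", 1:50),
                     class = "insecticide", n_jurisdictions = 5L,
                     min = 0.1, max = 10, median = 1,
                     stringsAsFactors = FALSE)
  al <- simulate_action_levels(spec, seed = 6)
  meds <- stats::setNames(al$ground_truth$median, al$ground_truth$pesticide)
  for (meth in c("arithmetic", "geometric")) {
    tol <- simulate_reference_tolerances(meds, 32, method = meth, seed = 7)
    st <- pesticide_stats(al$records, tol$tolerances)
    mf <- mean_fold_above_reference(st, method = meth)
    expect_equal(mf$mean_ratio, 32)
    expect_equal(mf$n, 50L)
  }
})

test_that("condition generator realizes planted coverage and totals", {
  spec <- data.frame(category = c("CatA", "CatB", "CatC"),
                     domain = c("neurological", "psychological",
                                "pain-and-injury"),
                     n_conditions = c(3L, 2L, 1L),
                     coverage = c(5L, 3L, 0L), stringsAsFactors = FALSE)
  cond <- simulate_conditions(spec, n_jurisdictions = 6, seed = 12)
  rec <- categorize_conditions(cond$conditions, cond$map)
  cov <- category_coverage(rec, unique(cond$map$category))
  expect_equal(cov$n_jurisdictions[match(c("CatA", "CatB", "CatC"),
                                         cov$category)], c(5L, 3L, 0L))
  dt <- domain_totals(rec)
  expect_equal(unname(dt$per_domain[c("neurological", "psychological")]),
               c(3L, 2L))
  expect_equal(dt$total, 5L)   # CatC uncovered, its condition never listed
  js <- jurisdiction_summary(rec)
  expect_equal(js$mean_conditions,
               round(cond$ground_truth$mean_conditions))
  ## determinism
  cond2 <- simulate_conditions(spec, n_jurisdictions = 6, seed = 12)
  expect_identical(cond$conditions, cond2$conditions)
})

test_that("seed is mandatory for every generator", {
  expect_error(simulate_ctd_tables(), "seed")
  expect_error(simulate_action_levels(default_action_level_spec()), "seed")
  expect_error(simulate_conditions(), "seed")
  expect_error(simulate_reference_tolerances(c(a = 1), 2), "seed")
})
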