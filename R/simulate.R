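## Synthetic-data generators.  Each emits tables in exactly the format the
## readers produce, together with machine-readable ground truth, so every
## downstream stage can be tested against planted answers without any
## external download.

#' Simulate CTD-like interaction tables with planted tetramers
#'
#' Generates the five curated interaction tables (chemical-gene,
#' chemical-phenotype, gene-phenotype, chemical-disease, gene-disease)
#' containing a planted set of complete CGPD tetramers plus decoy
#' quadruples that miss exactly one evidence line.  The planted set is
#' exact: at sampling time every candidate triple is checked against the
#' incremental closure of the pair sets and re-drawn if its pairs would
#' complete any non-planted quadruple, and the finished tables are
#' re-verified with a built-in brute-force enumeration before emission.
#' Decoys are built on fresh flanking chemicals and genes so their pairs
#' can never complete a quadruple elsewhere.
#'
#' Chemicals are split into an insecticide class (with subclass labels:
#' pyrethroid, organophosphate, organochlorine, carbamate, neonicotinoid,
#' phenylpyrazole) and a cannabinoid class.  Gene and phenotype pools are
#' partitioned so that the two classes share exactly `shared_genes` genes
#' and `shared_phenotypes` phenotypes (each class is forced to use its
#' whole shared pool).  Defaults emulate the structure of a CTD-scale
#' insecticide/cannabinoid seizure analysis at reduced tetramer count: 22
#' insecticides and 2 cannabinoids, 57 genes, 146 phenotypes, 150 + 25
#' planted tetramers, 8 shared genes and 4 shared phenotypes.
#'
#' @param n_chemicals total chemicals (insecticides + cannabinoids).
#' @param n_cannabinoids number of cannabinoid chemicals.
#' @param n_genes,n_phenotypes entity pool sizes.
#' @param n_tetramers named vector \code{c(insecticide=, cannabinoid=)} of
#'   planted tetramer counts, or a single total split 6:1.
#' @param quotas optional integer vector of per-chemical tetramer quotas
#'   (length \code{n_chemicals}); overrides \code{n_tetramers}.
#' @param decoy_density decoys per planted tetramer, in \[0, 1\].
#' @param shared_genes,shared_phenotypes exact number of genes/phenotypes
#'   used by both chemical classes.
#' @param n_cannabinoid_genes,n_cannabinoid_phenotypes pool sizes
#'   available to cannabinoid tetramers (must be at least the shared
#'   counts).
#' @param epilepsy_fraction fraction of the gene pool flagged as
#'   epilepsy-panel genes.
#' @param duplicate_fraction fraction of evidence rows emitted twice with
#'   distinct evidence text, to exercise evidence collapse.
#' @param disease disease endpoint key.
#' @param seed mandatory integer seed; identical seeds give identical
#'   tables.
#' @return list with \code{interactions} (named list of the five record
#'   data.frames), \code{classes}, \code{annotations},
#'   \code{epilepsy_genes}, \code{disease} and \code{ground_truth} (list:
#'   planted \code{tetramers} data.frame, \code{per_chemical} counts,
#'   \code{shared_genes}/\code{shared_phenotypes} counts,
#'   \code{n_genes_used}/\code{n_phenotypes_used}, \code{decoys}).
#' @export
simulate_ctd_tables <- function(n_chemicals = 24, n_cannabinoids = 2,
                                n_genes = 57, n_phenotypes = 146,
                                n_tetramers = c(insecticide = 150,
                                                cannabinoid = 25),
                                quotas = NULL, decoy_density = 0.5,
                                shared_genes = 8, shared_phenotypes = 4,
                                n_cannabinoid_genes = 12,
                                n_cannabinoid_phenotypes = 10,
                                epilepsy_fraction = 0.15,
                                duplicate_fraction = 0.1,
                                disease = "MESH:D012640", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(decoy_density >= 0, decoy_density <= 1,
            n_cannabinoids >= 1, n_chemicals > n_cannabinoids,
            shared_genes <= n_cannabinoid_genes,
            shared_phenotypes <= n_cannabinoid_phenotypes,
            n_cannabinoid_genes <= n_genes,
            n_cannabinoid_phenotypes <= n_phenotypes)
  set.seed(as.integer(seed))
  disease_key <- as_disease_key(disease)

  n_ins <- n_chemicals - n_cannabinoids
  chems <- sprintf("MESH:C%03d", seq_len(n_chemicals))
  genes <- sprintf("GENE:SYG%03d", seq_len(n_genes))
  phens <- sprintf("GO:%07d", seq_len(n_phenotypes))
  class_of <- rep(c("insecticide", "cannabinoid"), c(n_ins, n_cannabinoids))
  names(class_of) <- chems

  ## entity pools per class: cannabinoid pool = shared + cannabinoid-only,
  ## insecticide pool = shared + the remainder
  sg <- genes[seq_len(shared_genes)]
  cg_only <- genes[shared_genes + seq_len(n_cannabinoid_genes - shared_genes)]
  ig <- setdiff(genes, cg_only)
  cg <- c(sg, cg_only)
  sp <- phens[seq_len(shared_phenotypes)]
  cp_only <- phens[shared_phenotypes +
                   seq_len(n_cannabinoid_phenotypes - shared_phenotypes)]
  ip <- setdiff(phens, cp_only)
  cp <- c(sp, cp_only)

  quotas <- resolve_quotas(quotas, n_tetramers, class_of, n_ins,
                           n_cannabinoids)
  pairs <- new_pair_store()
  planted <- plant_tetramers(quotas, class_of, pairs, disease_key,
                             pools = list(
                               insecticide = list(genes = ig, phens = ip,
                                                  must_genes = sg,
                                                  must_phens = sp),
                               cannabinoid = list(genes = cg, phens = cp,
                                                  must_genes = sg,
                                                  must_phens = sp)))
  ## decoy count scales with the planted set but never vanishes for a
  ## decoy-only configuration
  decoys <- plant_decoys(round(decoy_density * max(nrow(planted),
                                                   n_chemicals)),
                         pairs, disease_key, phens)

  ## emission-time verification: brute-force enumeration of the pair
  ## tables must return exactly the planted quadruples
  closure <- enumerate_complete_triples(pairs, disease_key)
  if (!setequal(triple_id(closure), triple_id(planted))) {
    stop("internal error: generated tables do not realize the planted ",
         "tetramer set exactly", call. = FALSE)
  }

  interactions <- pair_store_to_tables(pairs, duplicate_fraction)
  annotations <- simulate_annotations(genes, epilepsy_fraction)
  classes <- chemical_class_table(class_of)

  per_chem <- table(planted$chemical)
  gt <- list(
    tetramers = planted[order(key_accession(planted$chemical),
                              key_accession(planted$gene),
                              key_accession(planted$phenotype)), ],
    per_chemical = stats::setNames(as.integer(per_chem), names(per_chem)),
    shared_genes = shared_genes,
    shared_phenotypes = shared_phenotypes,
    n_genes_used = length(unique(planted$gene)),
    n_phenotypes_used = length(unique(planted$phenotype)),
    n_tetramers = nrow(planted),
    decoys = decoys)
  rownames(gt$tetramers) <- NULL
  list(interactions = interactions, classes = classes,
       annotations = annotations,
       epilepsy_genes = unique(key_accession(
         annotations$gene_key[annotations$epilepsy])),
       disease = disease_key, ground_truth = gt)
}

resolve_quotas <- function(quotas, n_tetramers, class_of, n_ins, n_cab) {
  chems <- names(class_of)
  if (!is.null(quotas)) {
    stopifnot(length(quotas) == length(chems), all(quotas >= 0))
    return(stats::setNames(as.integer(quotas), chems))
  }
  if (length(n_tetramers) == 1L && is.null(names(n_tetramers))) {
    n_tetramers <- c(insecticide = round(n_tetramers * 6 / 7),
                     cannabinoid = n_tetramers - round(n_tetramers * 6 / 7))
  }
  out <- integer(length(chems))
  names(out) <- chems
  for (cls in c("insecticide", "cannabinoid")) {
    idx <- which(class_of == cls)
    total <- as.integer(n_tetramers[[cls]])
    if (total == 0L || length(idx) == 0L) next
    ## skewed allocation (a few chemicals dominate, as in curated data)
    w <- 1 / seq_along(idx)
    alloc <- as.vector(stats::rmultinom(1L, total, prob = w))
    out[idx] <- alloc
  }
  out
}

## Pair membership bookkeeping: one environment per evidence line, keyed
## "subject\rkey".
new_pair_store <- function() {
  s <- new.env(parent = emptyenv())
  for (nm in c("cg", "cp", "gp", "cd", "gd")) assign(nm, character(), s)
  s
}

pair_key <- function(a, b) paste(a, b, sep = "\r")

add_pair <- function(store, table, a, b) {
  cur <- get(table, store)
  k <- pair_key(a, b)
  if (!(k %in% cur)) assign(table, c(cur, k), store)
  invisible(NULL)
}

has_pair <- function(store, table, a, b) {
  pair_key(a, b) %in% get(table, store)
}

pair_frame <- function(store, table) {
  parts <- strsplit(get(table, store), "\r", fixed = TRUE)
  data.frame(subject = vapply(parts, `[[`, "", 1L),
             object = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

triple_id <- function(df) {
  paste(df$chemical, df$gene, df$phenotype, sep = "\r")
}

## Complete triples whose five pairs would all exist after adding the
## candidate's pairs, restricted to triples touching the candidate's
## entities (new completions can only involve a new pair).
local_completions <- function(store, cand, disease_key) {
  cg <- pair_frame(store, "cg"); cp <- pair_frame(store, "cp")
  gp <- pair_frame(store, "gp")
  cd <- vapply(strsplit(get("cd", store), "\r", fixed = TRUE), `[[`, "", 1L)
  gd <- vapply(strsplit(get("gd", store), "\r", fixed = TRUE), `[[`, "", 1L)
  ## tentative state
  cg <- unique(rbind(cg, data.frame(subject = cand$chemical,
                                    object = cand$gene)))
  cp <- unique(rbind(cp, data.frame(subject = cand$chemical,
                                    object = cand$phenotype)))
  gp <- unique(rbind(gp, data.frame(subject = cand$gene,
                                    object = cand$phenotype)))
  cd <- unique(c(cd, cand$chemical)); gd <- unique(c(gd, cand$gene))
  out <- list()
  ## triples through the new chem-gene pair
  p1 <- intersect(cp$object[cp$subject == cand$chemical],
                  gp$object[gp$subject == cand$gene])
  if (length(p1)) out[[1]] <- data.frame(chemical = cand$chemical,
                                         gene = cand$gene, phenotype = p1)
  ## triples through the new chem-phenotype pair
  g2 <- intersect(cg$object[cg$subject == cand$chemical],
                  gp$subject[gp$object == cand$phenotype])
  g2 <- g2[g2 %in% gd]
  if (length(g2)) out[[2]] <- data.frame(chemical = cand$chemical,
                                         gene = g2,
                                         phenotype = cand$phenotype)
  ## triples through the new gene-phenotype pair
  c3 <- intersect(cg$subject[cg$object == cand$gene],
                  cp$subject[cp$object == cand$phenotype])
  c3 <- c3[c3 %in% cd]
  if (length(c3)) out[[3]] <- data.frame(chemical = c3, gene = cand$gene,
                                         phenotype = cand$phenotype)
  unique(do.call(rbind, out))
}

## TRUE when planting (chem, g, p) completes no triple beyond the planted
## set plus the candidate itself
placement_ok <- function(pairs, planted, chem, g, p, disease_key) {
  cand <- data.frame(chemical = chem, gene = g, phenotype = p,
                     stringsAsFactors = FALSE)
  if (triple_id(cand) %in% triple_id(planted)) return(FALSE)
  comp <- local_completions(pairs, cand, disease_key)
  !length(setdiff(triple_id(comp), c(triple_id(planted), triple_id(cand))))
}

plant_tetramers <- function(quotas, class_of, pairs, disease_key, pools) {
  planted <- data.frame(chemical = character(), gene = character(),
                        phenotype = character(), stringsAsFactors = FALSE)
  ## queues of shared entities each class must still use
  queues <- lapply(pools, function(p)
    list(genes = sample(p$must_genes), phens = sample(p$must_phens)))
  for (cls in names(pools)) {
    need <- max(length(pools[[cls]]$must_genes),
                length(pools[[cls]]$must_phens))
    have <- sum(quotas[class_of[names(quotas)] == cls])
    if (have < need) {
      stop("infeasible quotas: the ", cls, " class needs at least ", need,
           " tetramers to cover its shared gene/phenotype pools",
           call. = FALSE)
    }
  }
  class_left <- vapply(names(pools), function(cls)
    sum(quotas[class_of[names(quotas)] == cls]), 0L)
  for (chem in names(quotas)) {
    cls <- class_of[[chem]]
    pool <- pools[[cls]]
    q <- quotas[[chem]]
    if (q > length(pool$genes) * length(pool$phens)) {
      stop("infeasible quota for ", chem, ": ", q, " tetramers exceed ",
           "the gene x phenotype capacity of its class pools",
           call. = FALSE)
    }
    placed <- 0L
    while (placed < q) {
      ## drain the shared-entity queues first; while the class still has
      ## slack the draw may fall back to the full pool, so an awkward
      ## queue entity can be deferred to a later placement
      qg <- queues[[cls]]$genes
      qp <- queues[[cls]]$phens
      force_g <- length(qg) >= class_left[[cls]]
      force_p <- length(qp) >= class_left[[cls]]
      pref_g <- if (length(qg)) qg else pool$genes
      pref_p <- if (length(qp)) qp else pool$phens
      full_g <- if (force_g) qg else pool$genes
      full_p <- if (force_p) qp else pool$phens
      draw1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)
      ok <- FALSE
      for (try in seq_len(80L)) {
        if (try <= 40L) {
          g <- draw1(pref_g); p <- draw1(pref_p)
        } else {
          g <- draw1(full_g); p <- draw1(full_p)
        }
        if (placement_ok(pairs, planted, chem, g, p, disease_key)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        ## exhaustive scan of the (shuffled) admissible grid before
        ## giving up
        grid <- expand.grid(g = sample(full_g), p = sample(full_p),
                            stringsAsFactors = FALSE)
        ## visit queue-satisfying cells first so shared entities are
        ## retired whenever any completion-free cell allows it
        grid <- grid[order(!(grid$g %in% qg), !(grid$p %in% qp)), ]
        hit <- 0L
        for (i in seq_len(nrow(grid))) {
          if (placement_ok(pairs, planted, chem, grid$g[i], grid$p[i],
                           disease_key)) {
            hit <- i
            break
          }
        }
        if (hit == 0L) {
          stop("infeasible quotas: could not place planted tetramers for ",
               chem, call. = FALSE)
        }
        g <- grid$g[hit]
        p <- grid$p[hit]
      }
      class_left[[cls]] <- class_left[[cls]] - 1L
      add_pair(pairs, "cg", chem, g)
      add_pair(pairs, "cp", chem, p)
      add_pair(pairs, "gp", g, p)
      add_pair(pairs, "cd", chem, disease_key)
      add_pair(pairs, "gd", g, disease_key)
      planted <- rbind(planted,
                       data.frame(chemical = chem, gene = g, phenotype = p,
                                  stringsAsFactors = FALSE))
      placed <- placed + 1L
      queues[[cls]]$genes <- setdiff(queues[[cls]]$genes, g)
      queues[[cls]]$phens <- setdiff(queues[[cls]]$phens, p)
    }
  }
  not_done <- vapply(queues, function(qq)
    length(qq$genes) + length(qq$phens), 0L)
  if (any(not_done > 0L)) {
    stop("infeasible quotas: shared gene/phenotype pools could not all ",
         "be used; increase the per-class tetramer counts", call. = FALSE)
  }
  planted$disease <- rep(disease_key, nrow(planted))
  planted
}

## Decoys: near-complete quadruples on fresh flanking entities, missing
## exactly one uniformly chosen evidence line.  Fresh chemicals/genes
## guarantee a decoy's pairs cannot complete any other quadruple.
plant_decoys <- function(n_decoys, pairs, disease_key, phens) {
  lines <- c("chem-gene", "chem-phenotype", "gene-phenotype",
             "chem-disease", "gene-disease")
  if (n_decoys <= 0L) {
    return(data.frame(chemical = character(), gene = character(),
                      phenotype = character(), missing_line = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    chemical = sprintf("MESH:CX%03d", seq_len(n_decoys)),
    gene = sprintf("GENE:SYGX%03d", seq_len(n_decoys)),
    phenotype = sample(phens, n_decoys, replace = TRUE),
    missing_line = sample(lines, n_decoys, replace = TRUE),
    stringsAsFactors = FALSE)
  for (i in seq_len(n_decoys)) {
    d <- out[i, ]
    if (d$missing_line != "chem-gene")
      add_pair(pairs, "cg", d$chemical, d$gene)
    if (d$missing_line != "chem-phenotype")
      add_pair(pairs, "cp", d$chemical, d$phenotype)
    if (d$missing_line != "gene-phenotype")
      add_pair(pairs, "gp", d$gene, d$phenotype)
    if (d$missing_line != "chem-disease")
      add_pair(pairs, "cd", d$chemical, disease_key)
    if (d$missing_line != "gene-disease")
      add_pair(pairs, "gd", d$gene, disease_key)
  }
  out
}

## Built-in brute-force oracle: enumerate every complete quadruple from
## the raw pair sets (used for the pre-emission exactness check).
enumerate_complete_triples <- function(pairs, disease_key) {
  cg <- pair_frame(pairs, "cg"); cp <- pair_frame(pairs, "cp")
  gp <- pair_frame(pairs, "gp")
  cd <- pair_frame(pairs, "cd"); gd <- pair_frame(pairs, "gd")
  cD <- cd$subject[cd$object == disease_key]
  gD <- gd$subject[gd$object == disease_key]
  out <- list()
  for (i in seq_len(nrow(cg))) {
    c0 <- cg$subject[i]; g0 <- cg$object[i]
    if (!(c0 %in% cD) || !(g0 %in% gD)) next
    p0 <- intersect(cp$object[cp$subject == c0], gp$object[gp$subject == g0])
    if (length(p0)) {
      out[[length(out) + 1L]] <- data.frame(chemical = c0, gene = g0,
                                            phenotype = p0,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chemical = character(), gene = character(),
                      phenotype = character(), stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

pair_store_to_tables <- function(pairs, duplicate_fraction) {
  mk <- function(table, kind) {
    df <- pair_frame(pairs, table)
    rec <- data.frame(kind = kind, subject_key = df$subject,
                      subject_name = NA_character_,
                      object_key = df$object, object_name = NA_character_,
                      evidence = "synthetic", stringsAsFactors = FALSE)
    if (duplicate_fraction > 0 && nrow(rec) > 0L) {
      n_dup <- round(duplicate_fraction * nrow(rec))
      if (n_dup > 0L) {
        dup <- rec[sample(nrow(rec), n_dup), , drop = FALSE]
        dup$evidence <- "synthetic-duplicate"
        rec <- rbind(rec, dup)
      }
    }
    rownames(rec) <- NULL
    rec
  }
  list(chem_gene = mk("cg", "chem-gene"),
       chem_phenotype = mk("cp", "chem-phenotype"),
       gene_phenotype = mk("gp", "gene-phenotype"),
       chem_disease = mk("cd", "chem-disease"),
       gene_disease = mk("gd", "gene-disease"))
}

SYNTHETIC_FUNCTIONS <- c("oxidation-reduction process",
                         "cholinergic signaling pathway",
                         "neuropeptide hormone activity",
                         "dopaminergic signaling pathway",
                         "MAPK signaling pathway")

simulate_annotations <- function(genes, epilepsy_fraction) {
  n_cat <- sample(1:2, length(genes), replace = TRUE)
  rows <- lapply(seq_along(genes), function(i) {
    data.frame(gene_key = genes[i],
               category = sample(SYNTHETIC_FUNCTIONS, n_cat[i]),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  flagged <- sample(genes, max(1L, round(epilepsy_fraction * length(genes))))
  ann$epilepsy <- ann$gene_key %in% flagged
  rownames(ann) <- NULL
  ann
}

chemical_class_table <- function(class_of) {
  subclasses <- c(rep("pyrethroid", 7), rep("organophosphate", 6),
                  rep("organochlorine", 4), rep("carbamate", 2),
                  rep("neonicotinoid", 2), "phenylpyrazole")
  ins <- names(class_of)[class_of == "insecticide"]
  cab <- names(class_of)[class_of == "cannabinoid"]
  sub <- rep(subclasses, length.out = length(ins))
  rbind(
    data.frame(chemical_key = ins, label = "insecticide",
               stringsAsFactors = FALSE),
    data.frame(chemical_key = ins, label = sub, stringsAsFactors = FALSE),
    data.frame(chemical_key = cab, label = "cannabinoid",
               stringsAsFactors = FALSE))
}

#' Simulate per-jurisdiction action-level tables with planted statistics
#'
#' Action levels are constructed, not sampled: for every pesticide the
#' realized minimum, maximum and (when given) median across jurisdictions
#' equal the planted values exactly.  An even jurisdiction count places
#' the planted median twice in the middle of the sorted levels; remaining
#' levels are log-spaced between the endpoints.  A zero-tolerance flag
#' inserts one jurisdiction at 0 ppm carrying the given LOQ.
#'
#' @param specs data.frame with columns \code{pesticide}, \code{class},
#'   \code{n_jurisdictions}, \code{min}, \code{max}, optional
#'   \code{median} (NA for free), optional logical \code{zero_tolerance}
#'   and \code{loq}.
#' @param n_jurisdiction_pool total number of jurisdiction labels to draw
#'   from (default 21).
#' @param seed mandatory integer seed.
#' @return list with \code{records} (action-level data.frame in
#'   [read_action_level_table()] format) and \code{ground_truth}
#'   (per-pesticide planted \code{min}/\code{median}/\code{max}/
#'   \code{fold_range}/\code{n_jurisdictions}).
#' @export
simulate_action_levels <- function(specs, n_jurisdiction_pool = 21, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  stopifnot(all(c("pesticide", "class", "n_jurisdictions", "min", "max")
                %in% names(specs)))
  if (!("median" %in% names(specs))) specs$median <- NA_real_
  if (!("zero_tolerance" %in% names(specs))) specs$zero_tolerance <- FALSE
  if (!("loq" %in% names(specs))) specs$loq <- NA_real_
  jur_pool <- sprintf("J%02d", seq_len(n_jurisdiction_pool))
  rec_list <- list()
  gt_list <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (!is.na(s$median) && (s$median < s$min || s$median > s$max)) {
      stop("planted median outside [min, max] for ", s$pesticide,
           call. = FALSE)
    }
    n_pos <- s$n_jurisdictions - as.integer(s$zero_tolerance)
    if (n_pos < 1L) stop("n_jurisdictions too small for ", s$pesticide,
                         call. = FALSE)
    lev <- construct_levels(n_pos, s$min, s$max,
                            if (s$zero_tolerance) NA_real_ else s$median)
    if (s$zero_tolerance) lev <- c(0, lev)
    if (s$n_jurisdictions > length(jur_pool)) {
      stop("n_jurisdictions exceeds the jurisdiction pool for ",
           s$pesticide, call. = FALSE)
    }
    jur <- sample(jur_pool, s$n_jurisdictions)
    rec_list[[i]] <- data.frame(
      jurisdiction = jur, pesticide = tolower(s$pesticide),
      class = tolower(s$class), product_type = "any",
      action_level = lev,
      loq = ifelse(lev == 0, s$loq, NA_real_),
      zero_tolerance = lev == 0, stringsAsFactors = FALSE)
    eff_min <- if (s$zero_tolerance && !is.na(s$loq))
      min(s$loq, s$min) else s$min
    gt_list[[i]] <- data.frame(
      pesticide = tolower(s$pesticide),
      min = if (s$zero_tolerance) 0 else s$min,
      median = stats::median(lev),
      max = s$max,
      fold_range = s$max / eff_min,
      n_jurisdictions = s$n_jurisdictions, stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rec_list),
       ground_truth = do.call(rbind, gt_list))
}

## n sorted levels in [a, b] with exact endpoints and (optionally) exact
## median m; interior points are log-spaced when positive.
construct_levels <- function(n, a, b, m = NA_real_) {
  stopifnot(n >= 1, a <= b)
  if (n == 1L) {
    if (!is.na(m) && m != a) stop("single level cannot realize the median",
                                  call. = FALSE)
    return(a)
  }
  span <- function(lo, hi, k) {
    if (k <= 0L) return(numeric())
    if (lo > 0) exp(seq(log(lo), log(hi), length.out = k + 2L))[-c(1L, k + 2L)]
    else seq(lo, hi, length.out = k + 2L)[-c(1L, k + 2L)]
  }
  if (is.na(m)) {
    if (a > 0) return(exp(seq(log(a), log(b), length.out = n)))
    return(seq(a, b, length.out = n))
  }
  if (n == 2L) {
    if (!isTRUE(all.equal((a + b) / 2, m))) {
      stop("two levels cannot realize median ", m, " with endpoints ",
           a, " and ", b, call. = FALSE)
    }
    return(c(a, b))
  }
  if (n %% 2L == 1L) {
    k <- (n - 3L) %/% 2L  # interior slots per side (excl. endpoints, median)
    lo_extra <- (n - 3L) %% 2L
    sort(c(a, span(a, m, k + lo_extra), m, span(m, b, k), b))
  } else {
    k <- (n - 4L) %/% 2L
    lo_extra <- (n - 4L) %% 2L
    sort(c(a, span(a, m, k + lo_extra), m, m, span(m, b, k), b))
  }
}

#' Simulate a reference-tolerance table with a planted mean fold-ratio
#'
#' Given planted median action levels, constructs per-pesticide reference
#' tolerances so that the chosen mean (arithmetic or geometric) of
#' median-to-tolerance ratios equals \code{target_mean_ratio} exactly:
#' raw lognormal ratios are rescaled to hit the target, and the tolerance
#' is the median divided by the ratio.
#'
#' @param medians named numeric vector of median action levels (ppm) per
#'   pesticide.
#' @param target_mean_ratio the planted mean ratio.
#' @param method \code{"arithmetic"} (default) or \code{"geometric"}.
#' @param seed mandatory integer seed.
#' @return list with \code{tolerances} (data.frame \code{pesticide},
#'   \code{lowest_tolerance}, \code{commodity}) and \code{ground_truth}
#'   (the planted ratios and their mean).
#' @export
simulate_reference_tolerances <- function(medians, target_mean_ratio,
                                          method = c("arithmetic",
                                                     "geometric"), seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  method <- match.arg(method)
  set.seed(as.integer(seed))
  stopifnot(!is.null(names(medians)), all(medians > 0),
            target_mean_ratio > 0)
  raw <- stats::rlnorm(length(medians), meanlog = 0, sdlog = 0.8)
  ratios <- switch(method,
    arithmetic = raw * target_mean_ratio / mean(raw),
    geometric = raw * target_mean_ratio / exp(mean(log(raw))))
  tol <- medians / ratios
  list(tolerances = data.frame(pesticide = tolower(names(medians)),
                               lowest_tolerance = unname(tol),
                               commodity = "synthetic",
                               stringsAsFactors = FALSE),
       ground_truth = list(ratios = stats::setNames(unname(ratios),
                                                    names(medians)),
                           mean_ratio = target_mean_ratio, method = method))
}

#' Simulate a qualifying-conditions table with planted coverage
#'
#' Builds a jurisdiction-by-condition table realizing an exact
#' per-category coverage vector (number of jurisdictions listing at least
#' one condition in the category) and exact per-domain distinct-condition
#' totals: every condition of a covered category is listed at least once,
#' distributed round-robin over the covered jurisdictions.
#'
#' @param category_spec data.frame with columns \code{category},
#'   \code{domain}, \code{n_conditions}, \code{coverage}; defaults
#'   emulate a 31-jurisdiction survey with 30 neurological, 9
#'   psychological and 17 pain-and-injury conditions in five categories.
#' @param n_jurisdictions total jurisdictions (default 31).
#' @param seed mandatory integer seed.
#' @return list with \code{conditions} ([read_conditions()] format),
#'   \code{map} (category-map data.frame) and \code{ground_truth}
#'   (planted \code{coverage}, \code{domain_totals},
#'   \code{per_jurisdiction} counts and their \code{mean}).
#' @export
simulate_conditions <- function(category_spec = default_category_spec(),
                                n_jurisdictions = 31, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  stopifnot(all(c("category", "domain", "n_conditions", "coverage") %in%
                names(category_spec)),
            all(category_spec$coverage <= n_jurisdictions))
  jurs <- sprintf("J%02d", seq_len(n_jurisdictions))
  rows <- list()
  map_rows <- list()
  for (i in seq_len(nrow(category_spec))) {
    s <- category_spec[i, ]
    conds <- normalize_condition(
      sprintf("%s condition %02d", s$category, seq_len(s$n_conditions)))
    map_rows[[i]] <- data.frame(condition = conds, category = s$category,
                                domain = tolower(s$domain),
                                stringsAsFactors = FALSE)
    if (s$coverage == 0L) next
    covered <- sample(jurs, s$coverage)
    ## every condition appears at least once; every covered jurisdiction
    ## lists at least one condition of the category
    n_assign <- max(s$n_conditions, s$coverage)
    assign_jur <- rep(covered, length.out = n_assign)
    assign_cond <- rep(conds, length.out = n_assign)
    rows[[i]] <- data.frame(jurisdiction = assign_jur,
                            condition = assign_cond,
                            condition_raw = assign_cond,
                            stringsAsFactors = FALSE)
  }
  conditions <- unique(do.call(rbind, rows))
  map <- do.call(rbind, map_rows)
  per <- vapply(split(conditions$condition, conditions$jurisdiction),
                function(x) length(unique(x)), 0L)
  used <- category_spec$coverage > 0L
  dom_tot <- vapply(split(category_spec$n_conditions[used],
                          tolower(category_spec$domain[used])), sum, 0)
  list(conditions = conditions, map = map,
       ground_truth = list(
         coverage = stats::setNames(category_spec$coverage,
                                    category_spec$category),
         domain_totals = dom_tot,
         total_conditions = sum(dom_tot),
         per_jurisdiction = per,
         mean_conditions = mean(per)))
}

#' @rdname simulate_conditions
#' @export
default_category_spec <- function() {
  data.frame(
    category = c("Movement Disorders", "Neurodegenerative Conditions",
                 "Other Neurological Conditions", "Psychiatric Conditions",
                 "Pain-Related Conditions"),
    domain = c("neurological", "neurological", "neurological",
               "psychological", "pain-and-injury"),
    n_conditions = c(12L, 10L, 8L, 9L, 17L),
    coverage = c(31L, 20L, 15L, 24L, 28L),
    stringsAsFactors = FALSE)
}
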