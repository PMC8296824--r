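#' Construct CGPD tetramers from five lines of curated evidence
#'
#' A chemical-gene-phenotype-disease (CGPD) tetramer is a quadruple
#' \eqn{(c, g, p, D)} supported by all five independently curated pairwise
#' evidence sets: chemical-gene, chemical-phenotype, gene-phenotype,
#' chemical-disease and gene-disease.  Each tetramer represents a
#' potential chemical-to-disease connection (e.g. insecticide to seizure)
#' in which the chemical and the gene are each linked to the same
#' phenotype and to the disease endpoint.
#'
#' Evidence is collapsed before construction: multiple records for the
#' same (kind, subject, object) count once, and tetramer identity is the
#' quadruple, never the evidence row.  Interaction direction or type
#' (increase/decrease, binding) is carried as metadata by the readers but
#' ignored by the membership tests.  The disease is a single fixed
#' endpoint per run; multi-disease analyses are sequential independent
#' runs.
#'
#' @param interactions named list of the five interaction data.frames as
#'   returned by [read_interaction_table()], under names \code{chem_gene},
#'   \code{chem_phenotype}, \code{gene_phenotype}, \code{chem_disease},
#'   \code{gene_disease} (hyphens accepted).
#' @param disease entity key of the disease endpoint (e.g.
#'   \code{"MESH:D012640"}), or a one-row [entity_ref()] data.frame.
#' @param chemical_scope character vector of chemical entity keys to
#'   restrict the construction to, or \code{NULL} (default) for every
#'   chemical present in the chemical-disease table.  Class-based scoping
#'   (insecticides, cannabinoids) is done by filtering with
#'   [read_chemical_classes()] output before calling.
#' @return an object of class \code{tetramer_set}: a list with elements
#'   \code{tetramers} (data.frame with columns \code{chemical},
#'   \code{gene}, \code{phenotype}, \code{disease}, plus display-name
#'   columns), \code{disease}, \code{scope} and \code{provenance}.
#'   Tetramers are deduplicated and ordered lexicographically by
#'   (chemical, gene, phenotype) accession, so construction is
#'   deterministic and idempotent.
#' @examples
#' tabs <- list(
#'   chem_gene = data.frame(subject_id = "C1", object_id = "G1"),
#'   chem_phenotype = data.frame(subject_id = "C1", object_id = "GO:1"),
#'   gene_phenotype = data.frame(subject_id = "G1", object_id = "GO:1"),
#'   chem_disease = data.frame(subject_id = "C1", object_id = "D012640"),
#'   gene_disease = data.frame(subject_id = "G1", object_id = "D012640"))
#' paths <- lapply(names(tabs), function(n) {
#'   f <- tempfile(fileext = ".tsv")
#'   write.table(tabs[[n]], f, sep = "\t", row.names = FALSE, quote = FALSE)
#'   f
#' })
#' names(paths) <- names(tabs)
#' ints <- Map(read_interaction_table, paths,
#'             c("chem-gene", "chem-phenotype", "gene-phenotype",
#'               "chem-disease", "gene-disease"))
#' ts <- build_tetramers(ints, disease = "MESH:D012640")
#' nrow(ts$tetramers)  # 1
#' @export
build_tetramers <- function(interactions, disease, chemical_scope = NULL) {
  ints <- canonical_interactions(interactions)
  disease_key <- as_disease_key(disease)

  ## unique evidence pairs per line (evidence collapse)
  cg <- unique(ints$chem_gene[, c("subject_key", "object_key")])
  cp <- unique(ints$chem_phenotype[, c("subject_key", "object_key")])
  gp <- unique(ints$gene_phenotype[, c("subject_key", "object_key")])
  cd <- ints$chem_disease
  gd <- ints$gene_disease
  chem_with_disease <- unique(cd$subject_key[cd$object_key == disease_key])
  gene_with_disease <- unique(gd$subject_key[gd$object_key == disease_key])

  if (length(chem_with_disease) == 0L && length(gene_with_disease) == 0L) {
    warning("disease ", disease_key,
            " absent from both chemical-disease and gene-disease evidence",
            call. = FALSE)
  }
  scope <- if (is.null(chemical_scope)) chem_with_disease
           else unique(as.character(chemical_scope))

  chems <- intersect(scope, chem_with_disease)
  tet <- empty_tetramer_frame(disease_key)
  if (length(chems) && length(gene_with_disease) &&
      nrow(cg) && nrow(cp) && nrow(gp)) {
    cg2 <- cg[cg$subject_key %in% chems &
              cg$object_key %in% gene_with_disease, , drop = FALSE]
    cp2 <- cp[cp$subject_key %in% chems, , drop = FALSE]
    names(cg2) <- c("chemical", "gene")
    names(cp2) <- c("chemical", "phenotype")
    cand <- merge(cg2, cp2, by = "chemical")
    if (nrow(cand)) {
      gp_keys <- paste(gp$subject_key, gp$object_key, sep = "\r")
      keep <- paste(cand$gene, cand$phenotype, sep = "\r") %in% gp_keys
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand)) {
      cand$disease <- disease_key
      cand <- unique(cand[, c("chemical", "gene", "phenotype", "disease")])
      ord <- order(key_accession(cand$chemical), key_accession(cand$gene),
                   key_accession(cand$phenotype))
      tet <- cand[ord, , drop = FALSE]
      rownames(tet) <- NULL
    }
  }
  names_lut <- display_name_lookup(ints)
  tet$chemical_name <- names_lut[tet$chemical]
  tet$gene_name <- names_lut[tet$gene]

  structure(list(tetramers = tet, disease = disease_key, scope = scope,
                 provenance = interaction_fingerprints(ints)),
            class = "tetramer_set")
}

empty_tetramer_frame <- function(disease_key) {
  data.frame(chemical = character(), gene = character(),
             phenotype = character(), disease = character(),
             stringsAsFactors = FALSE)
}

## Accept chem_gene / chem-gene style names; verify all five kinds present.
canonical_interactions <- function(interactions) {
  if (!is.list(interactions)) {
    stop("interactions must be a named list of five data.frames",
         call. = FALSE)
  }
  want <- gsub("-", "_", INTERACTION_KINDS)  # chem_gene, chem_phenotype, ...
  have <- gsub("-", "_", names(interactions))
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop("missing interaction table(s): ",
         paste(want[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- interactions[idx]
  names(out) <- want
  out
}

as_disease_key <- function(disease) {
  if (is.data.frame(disease)) return(disease$key[1L])
  disease <- as.character(disease)
  if (!grepl(":", disease, fixed = TRUE)) {
    stop("disease must be an entity key of the form 'NAMESPACE:accession'",
         call. = FALSE)
  }
  parts <- split_key(disease)
  entity_key(parts$namespace, parts$accession)
}

display_name_lookup <- function(ints) {
  all_keys <- unlist(lapply(ints, function(df) c(df$subject_key, df$object_key)),
                     use.names = FALSE)
  all_names <- unlist(lapply(ints, function(df) c(df$subject_name, df$object_name)),
                      use.names = FALSE)
  ok <- !is.na(all_names) & nzchar(all_names)
  lut <- all_names[ok][!duplicated(all_keys[ok])]
  names(lut) <- all_keys[ok][!duplicated(all_keys[ok])]
  lut
}

interaction_fingerprints <- function(ints) {
  lapply(ints, function(df) {
    list(n_records = nrow(df),
         n_pairs = nrow(unique(df[, c("subject_key", "object_key")])))
  })
}

#' @export
print.tetramer_set <- function(x, ...) {
  cat("CGPD tetramer set\n")
  cat("  disease endpoint:", x$disease, "\n")
  cat("  tetramers:", nrow(x$tetramers), "\n")
  ent <- distinct_entities(x)
  cat("  distinct chemicals:", ent[["chemicals"]],
      " genes:", ent[["genes"]], " phenotypes:", ent[["phenotypes"]], "\n")
  invisible(x)
}

#' @export
summary.tetramer_set <- function(object, ...) {
  counts <- tetramer_counts(object)
  out <- list(disease = object$disease, n_tetramers = nrow(object$tetramers),
              entities = distinct_entities(object),
              per_chemical = counts)
  class(out) <- "summary.tetramer_set"
  out
}

#' @export
print.summary.tetramer_set <- function(x, ...) {
  cat("CGPD tetramer set:", x$n_tetramers, "tetramers for", x$disease, "\n")
  cat("Entities:", x$entities[["chemicals"]], "chemicals,",
      x$entities[["genes"]], "genes,", x$entities[["phenotypes"]],
      "phenotypes\n")
  if (nrow(x$per_chemical)) {
    cat("Top chemicals by tetramer count:\n")
    print(utils::head(x$per_chemical, 10L), row.names = FALSE)
  }
  invisible(x)
}

#' Tetramer counts per chemical
#'
#' Number of tetramers containing each chemical, sorted descending (ties
#' broken by accession).  Chemicals with zero tetramers are omitted; the
#' counts sum to the total tetramer count.
#'
#' @param ts a \code{tetramer_set}.
#' @return data.frame with columns \code{chemical}, \code{chemical_name},
#'   \code{n_tetramers}.
#' @export
tetramer_counts <- function(ts) {
  stopifnot(inherits(ts, "tetramer_set"))
  tet <- ts$tetramers
  if (nrow(tet) == 0L) {
    return(data.frame(chemical = character(), chemical_name = character(),
                      n_tetramers = integer(), stringsAsFactors = FALSE))
  }
  cnt <- as.data.frame(table(chemical = tet$chemical),
                       stringsAsFactors = FALSE)
  names(cnt)[2L] <- "n_tetramers"
  cnt$chemical_name <- tet$chemical_name[match(cnt$chemical, tet$chemical)]
  cnt <- cnt[order(-cnt$n_tetramers, key_accession(cnt$chemical)),
             c("chemical", "chemical_name", "n_tetramers")]
  rownames(cnt) <- NULL
  cnt
}

#' Distinct entities in a tetramer set
#'
#' @param ts a \code{tetramer_set}.
#' @return named integer vector with elements \code{genes},
#'   \code{phenotypes}, \code{chemicals}: counts of unique accessions over
#'   the tetramer collection.
#' @export
distinct_entities <- function(ts) {
  stopifnot(inherits(ts, "tetramer_set"))
  tet <- ts$tetramers
  c(genes = length(unique(tet$gene)),
    phenotypes = length(unique(tet$phenotype)),
    chemicals = length(unique(tet$chemical)))
}

#' Entities shared between two tetramer sets
#'
#' Genes and phenotypes appearing in the tetramers of both sets, e.g. the
#' overlap between insecticide-scoped and cannabinoid-scoped tetramers for
#' the same disease endpoint.
#'
#' @param a,b \code{tetramer_set} objects with the same disease.
#' @return list with character vectors \code{genes} and \code{phenotypes}
#'   (sorted entity keys).
#' @export
shared_entities <- function(a, b) {
  stopifnot(inherits(a, "tetramer_set"), inherits(b, "tetramer_set"))
  if (!identical(a$disease, b$disease)) {
    stop("tetramer sets have different disease endpoints: ",
         a$disease, " vs ", b$disease, call. = FALSE)
  }
  list(genes = sort(intersect(unique(a$tetramers$gene),
                              unique(b$tetramers$gene))),
       phenotypes = sort(intersect(unique(a$tetramers$phenotype),
                                   unique(b$tetramers$phenotype))))
}

#' Overlap of tetramer genes with an epilepsy gene panel
#'
#' One row per gene appearing in the tetramer set, flagged when the gene
#' is on the epilepsy-variant panel (case-insensitive symbol match), with
#' its tetramer count and the contributing chemicals listed
#' lexicographically.
#'
#' @param ts a \code{tetramer_set}.
#' @param epilepsy_genes non-empty character vector of gene symbols (e.g.
#'   from [read_epilepsy_genes()]).
#' @return data.frame with columns \code{gene}, \code{gene_name},
#'   \code{epilepsy}, \code{n_tetramers}, \code{chemicals} (comma-joined
#'   accessions), sorted by descending tetramer count then gene symbol.
#' @export
epilepsy_overlap <- function(ts, epilepsy_genes) {
  stopifnot(inherits(ts, "tetramer_set"))
  if (length(epilepsy_genes) == 0L) {
    stop("epilepsy gene list must be non-empty", call. = FALSE)
  }
  tet <- ts$tetramers
  if (nrow(tet) == 0L) {
    return(data.frame(gene = character(), gene_name = character(),
                      epilepsy = logical(), n_tetramers = integer(),
                      chemicals = character(), stringsAsFactors = FALSE))
  }
  genes <- unique(tet$gene)
  n <- vapply(genes, function(g) sum(tet$gene == g), 0L)
  chems <- vapply(genes, function(g) {
    paste(sort(unique(key_accession(tet$chemical[tet$gene == g]))),
          collapse = ",")
  }, "")
  out <- data.frame(gene = genes,
                    gene_name = tet$gene_name[match(genes, tet$gene)],
                    epilepsy = symbol_in(genes, epilepsy_genes),
                    n_tetramers = n, chemicals = chems,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_tetramers, key_accession(out$gene)), ]
  rownames(out) <- NULL
  out
}

#' Write a tetramer set as TSV
#'
#' One tetramer per row with columns chemical, gene, phenotype, disease
#' (entity keys) plus display names where known.
#'
#' @param ts a \code{tetramer_set}.
#' @param path output path.
#' @export
write_tetramers <- function(ts, path) {
  stopifnot(inherits(ts, "tetramer_set"))
  utils::write.table(ts$tetramers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
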