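## Fixture builders and an independent brute-force oracle for the tetramer
## construction.  The oracle shares no code with the package internals: it
## enumerates every (chemical, gene, phenotype) triple with nested loops
## and performs the five membership tests on the raw record frames.

DIS <- "MESH:D012640"

## Build an interaction record frame from subject/object key vectors.
int_records <- function(kind, subjects, objects, evidence = "test") {
  data.frame(kind = kind, subject_key = subjects,
             subject_name = NA_character_,
             object_key = objects, object_name = NA_character_,
             evidence = evidence, stringsAsFactors = FALSE)
}

## Assemble the five-table list from pair matrices (2-column character).
five_tables <- function(cg, cp, gp, cd, gd) {
  list(chem_gene = int_records("chem-gene", cg[, 1], cg[, 2]),
       chem_phenotype = int_records("chem-phenotype", cp[, 1], cp[, 2]),
       gene_phenotype = int_records("gene-phenotype", gp[, 1], gp[, 2]),
       chem_disease = int_records("chem-disease", cd[, 1], cd[, 2]),
       gene_disease = int_records("gene-disease", gd[, 1], gd[, 2]))
}

## A minimal complete instance: one chemical, gene, phenotype, all five
## pairs present.
minimal_instance <- function(chem = "MESH:C1", gene = "GENE:G1",
                             phen = "GO:0000001") {
  five_tables(cbind(chem, gene), cbind(chem, phen), cbind(gene, phen),
              cbind(chem, DIS), cbind(gene, DIS))
}

## Full bipartite 2x2x2 instance: every admissible pair present.
full_2x2x2 <- function() {
  chems <- c("MESH:C1", "MESH:C2")
  genes <- c("GENE:G1", "GENE:G2")
  phens <- c("GO:0000001", "GO:0000002")
  grid_cg <- expand.grid(chems, genes, stringsAsFactors = FALSE)
  grid_cp <- expand.grid(chems, phens, stringsAsFactors = FALSE)
  grid_gp <- expand.grid(genes, phens, stringsAsFactors = FALSE)
  five_tables(as.matrix(grid_cg), as.matrix(grid_cp), as.matrix(grid_gp),
              cbind(chems, DIS), cbind(genes, DIS))
}

## Independent oracle: exhaustive triple loop with five membership tests.
oracle_tetramers <- function(ints, disease = DIS, scope = NULL) {
  has <- function(df, s, o) {
    any(df$subject_key == s & df$object_key == o)
  }
  chems <- unique(c(ints$chem_gene$subject_key,
                    ints$chem_phenotype$subject_key,
                    ints$chem_disease$subject_key))
  if (!is.null(scope)) chems <- intersect(chems, scope)
  genes <- unique(c(ints$chem_gene$object_key,
                    ints$gene_phenotype$subject_key,
                    ints$gene_disease$subject_key))
  phens <- unique(c(ints$chem_phenotype$object_key,
                    ints$gene_phenotype$object_key))
  found <- character()
  for (c0 in chems) for (g0 in genes) for (p0 in phens) {
    if (has(ints$chem_gene, c0, g0) &&
        has(ints$chem_phenotype, c0, p0) &&
        has(ints$gene_phenotype, g0, p0) &&
        has(ints$chem_disease, c0, disease) &&
        has(ints$gene_disease, g0, disease)) {
      found <- c(found, paste(c0, g0, p0, sep = "|"))
    }
  }
  sort(found)
}

tetramer_ids <- function(ts) {
  sort(paste(ts$tetramers$chemical, ts$tetramers$gene,
             ts$tetramers$phenotype, sep = "|"))
}

## Random sparse instance for property tests: independent Bernoulli pairs.
random_instance <- function(nc, ng, np, density = 0.3,
                            disease_density = 0.8) {
  chems <- sprintf("MESH:R%02d", seq_len(nc))
  genes <- sprintf("GENE:RG%02d", seq_len(ng))
  phens <- sprintf("GO:%07d", seq_len(np))
  pick_pairs <- function(a, b, d) {
    grid <- expand.grid(a, b, stringsAsFactors = FALSE)
    grid[stats::runif(nrow(grid)) < d, , drop = FALSE]
  }
  cg <- pick_pairs(chems, genes, density)
  cp <- pick_pairs(chems, phens, density)
  gp <- pick_pairs(genes, phens, density)
  cd <- chems[stats::runif(nc) < disease_density]
  gd <- genes[stats::runif(ng) < disease_density]
  ## guard against empty frames (cbind on length-0 vectors)
  pad <- function(m, fallback) if (nrow(m) == 0L) fallback else as.matrix(m)
  five_tables(pad(cg, cbind("MESH:R00", "GENE:RG00")),
              pad(cp, cbind("MESH:R00", "GO:0000000")),
              pad(gp, cbind("GENE:RG00", "GO:0000000")),
              if (length(cd)) cbind(cd, DIS) else cbind("MESH:R00", DIS),
              if (length(gd)) cbind(gd, DIS) else cbind("GENE:RG00", DIS))
}

## Write the five tables to TSV files; returns named list of paths.
write_five <- function(ints, dir = withr::local_tempdir(.local_envir =
                                                          parent.frame())) {
  paths <- lapply(names(ints), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_interaction_table(ints[[nm]], p)
    p
  })
  names(paths) <- names(ints)
  paths
}
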