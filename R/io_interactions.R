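## Interaction-table I/O in the CTD flat-file dialect: tab-separated with a
## header row, '#'-prefixed comment lines tolerated and skipped, column
## names matched case-insensitively, optional gzip.

INTERACTION_KINDS <- c("chem-gene", "chem-phenotype", "gene-phenotype",
                       "chem-disease", "gene-disease")

## Default namespace per side of each interaction kind; used when a table
## omits explicit namespace columns.
kind_namespaces <- function(kind) {
  switch(kind,
    "chem-gene"      = c(subject = "MESH", object = "GENE"),
    "chem-phenotype" = c(subject = "MESH", object = "GO"),
    "gene-phenotype" = c(subject = "GENE", object = "GO"),
    "chem-disease"   = c(subject = "MESH", object = "MESH"),
    "gene-disease"   = c(subject = "GENE", object = "MESH"),
    stop("unknown interaction kind: ", kind, call. = FALSE))
}

check_kind <- function(kind) {
  kind <- match.arg(kind, INTERACTION_KINDS)
  kind
}

## Read a delimited text file skipping '#' comment lines; returns a
## data.frame with case-preserved headers, or NULL when no data rows remain.
read_commented_delim <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(NULL)
  utils::read.table(text = lines, sep = sep, header = TRUE,
                    quote = "\"", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    comment.char = "")
}

## Locate a column by case-insensitive name; returns values or NULL.
pick_column <- function(df, name) {
  hit <- which(tolower(names(df)) == tolower(name))
  if (length(hit) == 0L) return(NULL)
  df[[hit[1L]]]
}

require_column <- function(df, name, path) {
  v <- pick_column(df, name)
  if (is.null(v)) {
    stop("missing required column '", name, "' in ", path, call. = FALSE)
  }
  v
}

#' Read a curated interaction table
#'
#' Reads one of the five evidence tables (chemical-gene, chemical-phenotype,
#' gene-phenotype, chemical-disease, gene-disease) from a tab-separated
#' file in the CTD flat-file dialect: a header row, \code{#}-prefixed
#' comment lines skipped, column names matched case-insensitively, optional
#' gzip compression.  Required columns are \code{subject_id} and
#' \code{object_id}; \code{subject_ns}, \code{object_ns},
#' \code{subject_name}, \code{object_name} and \code{evidence} are
#' optional, with namespaces defaulting per interaction kind (chemicals
#' and diseases MESH, genes GENE, phenotypes GO).
#'
#' Identifiers are trimmed and case-normalized (gene symbols upper-cased);
#' row order is preserved; duplicate rows are kept on read and collapsed
#' downstream by the tetramer engine.
#'
#' @param path path to the TSV file (optionally \code{.gz}).
#' @param kind one of \code{"chem-gene"}, \code{"chem-phenotype"},
#'   \code{"gene-phenotype"}, \code{"chem-disease"}, \code{"gene-disease"}.
#' @return a data.frame of interaction records with columns \code{kind},
#'   \code{subject_key}, \code{subject_name}, \code{object_key},
#'   \code{object_name}, \code{evidence}.
#' @seealso [write_interaction_table()], [build_tetramers()]
#' @export
read_interaction_table <- function(path, kind) {
  kind <- check_kind(kind)
  df <- read_commented_delim(path, sep = "\t")
  if (is.null(df)) {
    warning("no data rows (after comments) in ", path, call. = FALSE)
    return(empty_interactions(kind))
  }
  ns <- kind_namespaces(kind)
  sid <- require_column(df, "subject_id", path)
  oid <- require_column(df, "object_id", path)
  sns <- pick_column(df, "subject_ns"); if (is.null(sns)) sns <- ns[["subject"]]
  ons <- pick_column(df, "object_ns");  if (is.null(ons)) ons <- ns[["object"]]
  snm <- pick_column(df, "subject_name"); if (is.null(snm)) snm <- NA_character_
  onm <- pick_column(df, "object_name");  if (is.null(onm)) onm <- NA_character_
  ev  <- pick_column(df, "evidence"); if (is.null(ev)) ev <- NA_character_
  subj <- entity_ref(sns, sid, snm)
  obj <- entity_ref(ons, oid, onm)
  data.frame(kind = kind,
             subject_key = subj$key, subject_name = subj$display_name,
             object_key = obj$key, object_name = obj$display_name,
             evidence = as.character(ev),
             stringsAsFactors = FALSE)
}

empty_interactions <- function(kind) {
  data.frame(kind = character(), subject_key = character(),
             subject_name = character(), object_key = character(),
             object_name = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' Write a curated interaction table
#'
#' Writes records read (or built) in the format [read_interaction_table()]
#' consumes, so that a write/read round trip is the identity on the
#' canonicalized records.
#'
#' @param records data.frame as returned by [read_interaction_table()].
#' @param path output path (plain TSV; \code{.gz} suffix writes gzip).
#' @export
write_interaction_table <- function(records, path) {
  sk <- split_key(records$subject_key)
  ok <- split_key(records$object_key)
  out <- data.frame(subject_ns = sk$namespace, subject_id = sk$accession,
                    subject_name = records$subject_name,
                    object_ns = ok$namespace, object_id = ok$accession,
                    object_name = records$object_name,
                    evidence = records$evidence,
                    stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a chemical class table
#'
#' Maps chemicals to class labels (e.g. insecticide, cannabinoid, and
#' subclasses such as pyrethroid or organophosphate).  A chemical may carry
#' several labels (one row each); labels are case-normalized to lower case.
#'
#' @param path TSV/CSV with columns \code{chemical_id}, \code{label} and
#'   optionally \code{chemical_ns} (default \code{MESH}).
#' @return data.frame with columns \code{chemical_key}, \code{label}.
#' @export
read_chemical_classes <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read_commented_delim(path, sep)
  if (is.null(df)) {
    return(data.frame(chemical_key = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  id <- require_column(df, "chemical_id", path)
  ns <- pick_column(df, "chemical_ns"); if (is.null(ns)) ns <- "MESH"
  lab <- require_column(df, "label", path)
  data.frame(chemical_key = entity_key(ns, id),
             label = tolower(trimws(lab)), stringsAsFactors = FALSE)
}

#' Read a gene functional-annotation table
#'
#' Maps genes to functional category labels (as produced by annotation
#' services such as DAVID and consumed here as a plain input table).  A
#' gene may belong to several categories.
#'
#' @param path TSV/CSV with columns \code{gene} (symbol) and
#'   \code{category}; an optional logical-like \code{epilepsy} column
#'   flags epilepsy-variant genes (default false).
#' @return data.frame with columns \code{gene_key}, \code{category},
#'   \code{epilepsy}.
#' @export
read_gene_annotations <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read_commented_delim(path, sep)
  if (is.null(df)) {
    return(data.frame(gene_key = character(), category = character(),
                      epilepsy = logical(), stringsAsFactors = FALSE))
  }
  gene <- require_column(df, "gene", path)
  category <- require_column(df, "category", path)
  epi <- pick_column(df, "epilepsy")
  epi <- if (is.null(epi)) FALSE else as.logical(epi) %in% TRUE
  data.frame(gene_key = entity_key("GENE", gene),
             category = trimws(category), epilepsy = epi,
             stringsAsFactors = FALSE)
}

#' Read an epilepsy gene list
#'
#' Accepts either one gene symbol per line or a two-column TSV whose first
#' column holds the symbol; \code{#} comments are skipped.  Symbols are
#' matched case-insensitively downstream.
#'
#' @param path path to the list.
#' @return character vector of upper-cased gene symbols.
#' @export
read_epilepsy_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  syms <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  syms <- toupper(trimws(syms))
  syms <- unique(syms[nzchar(syms)])
  if (length(syms) && identical(syms[1L], "GENE")) syms <- syms[-1L]
  syms
}
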