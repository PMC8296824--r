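#' Summarize gene connections per biological function
#'
#' Reproduces the per-pathway gene-connection table: for each biological
#' function and each gene annotated to it, the number of distinct
#' insecticides whose tetramers touch the gene, the gene's insecticide and
#' cannabinoid tetramer counts, and whether the gene is on the
#' epilepsy-variant panel.  Epilepsy-panel genes annotated to a function
#' are retained even when they occur in no tetramer (zero-count rows);
#' other genes without tetramers are dropped.  Genes annotated to several
#' functions appear under each.
#'
#' Per-function totals count \emph{distinct} insecticides across the
#' function's genes (the same insecticide hitting two genes counts once),
#' while total tetramers sum both chemical classes over the function's
#' rows.
#'
#' @param insecticide_ts,cannabinoid_ts \code{tetramer_set} objects for
#'   the two chemical classes, sharing the same disease endpoint.
#' @param annotations gene annotation table ([read_gene_annotations()]).
#' @param epilepsy_genes character vector of panel gene symbols (may be
#'   empty, in which case no zero-count rows are added).
#' @return object of class \code{pathway_summary}: list with data.frames
#'   \code{rows} (columns \code{pathway}, \code{gene}, \code{gene_name},
#'   \code{insecticide_count}, \code{insecticide_tetramers},
#'   \code{cannabinoid_tetramers}, \code{epilepsy}; grouped by pathway and
#'   sorted by descending insecticide tetramer count) and \code{totals}
#'   (columns \code{pathway}, \code{n_insecticides}, \code{n_genes},
#'   \code{total_tetramers}).
#' @export
summarize_by_function <- function(insecticide_ts, cannabinoid_ts,
                                  annotations, epilepsy_genes = character()) {
  stopifnot(inherits(insecticide_ts, "tetramer_set"),
            inherits(cannabinoid_ts, "tetramer_set"))
  if (!identical(insecticide_ts$disease, cannabinoid_ts$disease)) {
    stop("tetramer sets have different disease endpoints: ",
         insecticide_ts$disease, " vs ", cannabinoid_ts$disease,
         call. = FALSE)
  }
  ins <- insecticide_ts$tetramers
  cab <- cannabinoid_ts$tetramers
  ann <- unique(annotations[, c("gene_key", "category")])
  touched <- union(unique(ins$gene), unique(cab$gene))
  is_epi <- symbol_in(ann$gene_key, epilepsy_genes)
  keep <- ann$gene_key %in% touched | is_epi
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) == 0L) {
    rows <- data.frame(pathway = character(), gene = character(),
                       gene_name = character(), insecticide_count = integer(),
                       insecticide_tetramers = integer(),
                       cannabinoid_tetramers = integer(), epilepsy = logical(),
                       stringsAsFactors = FALSE)
    totals <- data.frame(pathway = character(), n_insecticides = integer(),
                         n_genes = integer(), total_tetramers = integer(),
                         stringsAsFactors = FALSE)
    return(structure(list(rows = rows, totals = totals),
                     class = "pathway_summary"))
  }
  names_lut <- c(stats::setNames(ins$gene_name, ins$gene),
                 stats::setNames(cab$gene_name, cab$gene))
  rows <- data.frame(
    pathway = ann$category,
    gene = ann$gene_key,
    gene_name = unname(names_lut[ann$gene_key]),
    insecticide_count = vapply(ann$gene_key, function(g)
      length(unique(ins$chemical[ins$gene == g])), 0L),
    insecticide_tetramers = vapply(ann$gene_key, function(g)
      sum(ins$gene == g), 0L),
    cannabinoid_tetramers = vapply(ann$gene_key, function(g)
      sum(cab$gene == g), 0L),
    epilepsy = symbol_in(ann$gene_key, epilepsy_genes),
    stringsAsFactors = FALSE)
  rows <- rows[order(rows$pathway, -rows$insecticide_tetramers,
                     key_accession(rows$gene)), ]
  rownames(rows) <- NULL

  n_insecticides <- vapply(split(rows$gene, rows$pathway), function(genes)
    length(unique(ins$chemical[ins$gene %in% genes])), 0L)
  totals <- pathway_totals(rows)
  totals$n_insecticides <- as.integer(n_insecticides[totals$pathway])
  totals <- totals[, c("pathway", "n_insecticides", "n_genes",
                       "total_tetramers")]
  structure(list(rows = rows, totals = totals), class = "pathway_summary")
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat("Pathway summary:", nrow(x$rows), "gene rows in",
      nrow(x$totals), "functions\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Per-function totals from a gene-connection row table
#'
#' Aggregates a row table (as in [summarize_by_function()] output, or a
#' published table read from file) into per-function gene counts and total
#' tetramer counts.  Total tetramers sum the insecticide and cannabinoid
#' tetramer columns over the function's rows; the distinct-insecticide
#' total is left \code{NA} here because it is not recoverable from
#' per-gene counts alone (the same insecticide may touch several genes).
#'
#' @param rows data.frame with columns \code{pathway},
#'   \code{insecticide_tetramers}, \code{cannabinoid_tetramers}.
#' @return data.frame with columns \code{pathway}, \code{n_insecticides}
#'   (NA), \code{n_genes}, \code{total_tetramers}.
#' @export
pathway_totals <- function(rows) {
  stopifnot(all(c("pathway", "insecticide_tetramers",
                  "cannabinoid_tetramers") %in% names(rows)))
  paths <- unique(rows$pathway)
  data.frame(
    pathway = paths,
    n_insecticides = NA_integer_,
    n_genes = vapply(paths, function(p) sum(rows$pathway == p), 0L),
    total_tetramers = vapply(paths, function(p) {
      sel <- rows$pathway == p
      as.integer(sum(rows$insecticide_tetramers[sel]) +
                 sum(rows$cannabinoid_tetramers[sel]))
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a pathway summary as CSV
#'
#' Column order mirrors the published table: function, gene name, symbol,
#' insecticide count, insecticide tetramer count, cannabinoid tetramer
#' count, epilepsy flag.
#'
#' @param ps a \code{pathway_summary}.
#' @param path output CSV path.
#' @export
write_pathway_summary <- function(ps, path) {
  stopifnot(inherits(ps, "pathway_summary"))
  out <- data.frame(pathway = ps$rows$pathway,
                    gene_name = ps$rows$gene_name,
                    symbol = key_accession(ps$rows$gene),
                    insecticide_count = ps$rows$insecticide_count,
                    insecticide_tetramers = ps$rows$insecticide_tetramers,
                    cannabinoid_tetramers = ps$rows$cannabinoid_tetramers,
                    epilepsy = ps$rows$epilepsy,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
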