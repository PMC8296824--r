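#' Build the tetramer-weighted bipartite edge list
#'
#' One edge per distinct (chemical, gene) pair appearing in any tetramer,
#' weighted by the number of tetramers containing that pair.  Edge weights
#' therefore sum to the total tetramer count.
#'
#' @param ts a \code{tetramer_set}.
#' @return data.frame of class \code{c("bipartite_edges", "data.frame")}
#'   with columns \code{chemical}, \code{gene}, \code{weight} plus display
#'   names, sorted by descending weight then accessions.
#' @export
build_edge_list <- function(ts) {
  stopifnot(inherits(ts, "tetramer_set"))
  tet <- ts$tetramers
  if (nrow(tet) == 0L) {
    out <- data.frame(chemical = character(), gene = character(),
                      weight = integer(), chemical_name = character(),
                      gene_name = character(), stringsAsFactors = FALSE)
    class(out) <- c("bipartite_edges", "data.frame")
    return(out)
  }
  agg <- stats::aggregate(list(weight = rep(1L, nrow(tet))),
                          by = list(chemical = tet$chemical, gene = tet$gene),
                          FUN = sum)
  agg$chemical_name <- tet$chemical_name[match(agg$chemical, tet$chemical)]
  agg$gene_name <- tet$gene_name[match(agg$gene, tet$gene)]
  agg <- agg[order(-agg$weight, key_accession(agg$chemical),
                   key_accession(agg$gene)), ]
  rownames(agg) <- NULL
  class(agg) <- c("bipartite_edges", "data.frame")
  agg
}

#' Weighted degree centrality of the bipartite network
#'
#' For each node (chemical or gene) incident to at least one edge, the sum
#' of incident edge weights.  For a chemical this equals its tetramer
#' count; summed over either partition it equals the total tetramer count.
#'
#' @param edges edge list from [build_edge_list()].
#' @return data.frame with columns \code{node}, \code{partition}
#'   (\code{"chemical"} or \code{"gene"}), \code{weighted_degree}, sorted
#'   by descending weighted degree then accession.
#' @export
weighted_degree <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(node = character(), partition = character(),
                      weighted_degree = integer(), stringsAsFactors = FALSE))
  }
  chem <- tapply(edges$weight, edges$chemical, sum)
  gene <- tapply(edges$weight, edges$gene, sum)
  out <- data.frame(
    node = c(names(chem), names(gene)),
    partition = rep(c("chemical", "gene"), c(length(chem), length(gene))),
    weighted_degree = as.integer(c(chem, gene)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$weighted_degree, key_accession(out$node)), ]
  rownames(out) <- NULL
  out
}

#' Assign one display category per gene
#'
#' Genes annotated to several biological functions get a single display
#' category: the first of the gene's categories found in an explicit
#' priority order, else \code{"unannotated"}.  The assignment is
#' deterministic and independent of the annotation table's row order.
#'
#' @param edges edge list from [build_edge_list()].
#' @param annotations gene annotation table from [read_gene_annotations()].
#' @param priority non-empty character vector of category labels, highest
#'   priority first.
#' @return the edge list with an added \code{category} column (one label
#'   per gene).
#' @export
color_by_function <- function(edges, annotations, priority) {
  if (length(priority) == 0L) {
    stop("priority category list must be non-empty", call. = FALSE)
  }
  edges$category <- vapply(edges$gene, function(g) {
    cats <- unique(annotations$category[annotations$gene_key == g])
    hit <- priority[priority %in% cats]
    if (length(hit)) hit[1L] else "unannotated"
  }, "")
  edges
}
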