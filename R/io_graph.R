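#' Export the bipartite network
#'
#' Writes the chemical-by-gene network as GraphML (via \pkg{igraph}) or as
#' an edge-list CSV.  Every node carries a \code{partition} attribute
#' (chemical vs gene) and a \code{weighted_degree} attribute (raw sum of
#' incident edge weights, exported for consumers that size nodes); genes
#' carry a \code{category} attribute from the annotation table, defaulting
#' to \code{"unannotated"}; edges carry their integer weight.
#'
#' @param edges edge list from [build_edge_list()] (a \code{category}
#'   column from [color_by_function()] is used when present).
#' @param annotations gene annotation table ([read_gene_annotations()]);
#'   ignored when `edges` already has a `category` column.  May be `NULL`.
#' @param path output path.
#' @param format \code{"graphml"} or \code{"csv"}.
#' @param priority category priority order passed to [color_by_function()]
#'   when categories have to be derived here; defaults to the sorted set
#'   of annotation categories.
#' @return the path, invisibly.
#' @seealso [read_edge_list()] for the CSV round trip.
#' @export
write_graph <- function(edges, annotations = NULL, path,
                        format = c("graphml", "csv"), priority = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown graph format: ",
                                              format[1L], call. = FALSE))
  if (!("category" %in% names(edges))) {
    if (!is.null(annotations) && nrow(annotations)) {
      if (is.null(priority)) priority <- sort(unique(annotations$category))
      edges <- color_by_function(edges, annotations, priority)
    } else {
      edges$category <- "unannotated"
    }
  }
  if (format == "csv") {
    out <- data.frame(chemical = edges$chemical, gene = edges$gene,
                      weight = edges$weight, category = edges$category,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  g <- as_igraph(edges)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert an edge list to an igraph bipartite graph
#'
#' @param edges edge list from [build_edge_list()], optionally with a
#'   \code{category} column.
#' @return an \pkg{igraph} graph with vertex attributes \code{partition},
#'   \code{type} (logical, TRUE for genes, the bipartite convention),
#'   \code{category}, \code{weighted_degree} and edge attribute
#'   \code{weight}.
#' @export
as_igraph <- function(edges) {
  chems <- unique(edges$chemical)
  genes <- unique(edges$gene)
  verts <- data.frame(
    name = c(chems, genes),
    partition = rep(c("chemical", "gene"), c(length(chems), length(genes))),
    type = rep(c(FALSE, TRUE), c(length(chems), length(genes))),
    stringsAsFactors = FALSE)
  cat_col <- if ("category" %in% names(edges)) edges$category else
    rep("unannotated", nrow(edges))
  verts$category <- ifelse(verts$partition == "gene",
                           cat_col[match(verts$name, edges$gene)], NA)
  verts$category[verts$partition == "gene" & is.na(verts$category)] <-
    "unannotated"
  el <- data.frame(from = edges$chemical, to = edges$gene,
                   weight = edges$weight, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
  igraph::V(g)$weighted_degree <- igraph::strength(g, weights =
                                                     igraph::E(g)$weight)
  g
}

#' Read an exported edge-list CSV
#'
#' Round-trip reader for the CSV written by [write_graph()].
#'
#' @param path CSV path.
#' @return data.frame with columns \code{chemical}, \code{gene},
#'   \code{weight}, \code{category}.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(weight = "integer"))
  need <- c("chemical", "gene", "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column '", miss[1L], "' in ", path, call. = FALSE)
  }
  df
}
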