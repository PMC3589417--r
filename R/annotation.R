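## Functional categorization and interaction-network summarization.
## Annotation and edge evidence are consumed as static user-supplied tables
## (exports from GO/DAVID/STRING-style resources), never queried live, so a
## run is reproducible against a fixed annotation version.

#' Functional-category breakdown of called interactors
#'
#' Counts interactors per primary biological-process category (one category
#' per protein; the summary is a partition) and reports integer-rounded
#' percentages of the interactor total. Proteins absent from the annotation
#' table are reported as \code{"unannotated"}.
#'
#' @param interactors Character vector of interactor accessions.
#' @param annotation \code{data.frame} with columns \code{accession},
#'   \code{category}.
#' @return \code{data.frame} with columns \code{category}, \code{count},
#'   \code{percentage}, ordered by decreasing count then category.
#' @examples
#' ann <- data.frame(accession = "P1", category = "signal transduction")
#' categorizeInteractors(c("P1", "P2"), ann)
#' @export
categorizeInteractors <- function(interactors, annotation) {
  if (!length(interactors))
    return(data.frame(category = character(), count = integer(),
                      percentage = numeric()))
  cat_ <- annotation$category[match(interactors, annotation$accession)]
  cat_[is.na(cat_) | !nzchar(cat_)] <- "unannotated"
  tab <- table(cat_)
  out <- data.frame(category = names(tab), count = as.integer(tab),
                    percentage = round(100 * as.integer(tab) / length(interactors)))
  out[order(-out$count, out$category), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Build the bait-centred interactor network
#'
#' Constructs an undirected graph over the bait, the called interactors and
#' any additional partners referenced by the evidence edge table. The bait
#' is connected to every called interactor (the pulldown itself is the
#' direct-association evidence); supplied edges add the between-interactor
#' structure. Self-loops and duplicate/reversed edges are collapsed;
#' malformed edge rows (missing endpoint) are skipped with a warning.
#'
#' @param interactors Character vector of interactor accessions.
#' @param bait_accession Bait accession.
#' @param edges Optional \code{data.frame} with columns \code{source},
#'   \code{target} and optionally \code{weight}.
#' @param connect_bait Add a bait--interactor edge for every interactor.
#' @return An undirected \code{\link[igraph]{igraph}} graph.
#' @examples
#' g <- buildNetwork(c("P1", "P2", "P3"), "BAIT")
#' igraph::ecount(g)  # 3
#' @export
buildNetwork <- function(interactors, bait_accession, edges = NULL,
                         connect_bait = TRUE) {
  el <- data.frame(source = character(), target = character())
  if (connect_bait && length(interactors))
    el <- data.frame(source = bait_accession, target = interactors)
  if (!is.null(edges) && nrow(edges)) {
    bad <- is.na(edges$source) | is.na(edges$target) |
      !nzchar(edges$source) | !nzchar(edges$target)
    if (any(bad))
      warning(sum(bad), " malformed edge row(s) skipped")
    el <- rbind(el, edges[!bad, c("source", "target"), drop = FALSE])
  }
  nodes <- unique(c(bait_accession, interactors, el$source, el$target))
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Rank network nodes by degree
#'
#' Nodes sorted by decreasing degree on the undirected graph; ties broken
#' by lexicographic node identifier. In a pulldown-derived network the bait
#' is expected to be the most interconnected node.
#'
#' @param graph An \code{\link[igraph]{igraph}} graph.
#' @return \code{data.frame} with columns \code{node}, \code{degree}.
#' @examples
#' g <- buildNetwork(c("P1", "P2"), "BAIT")
#' degreeRanking(g)$node[1]  # "BAIT"
#' @export
degreeRanking <- function(graph) {
  if (igraph::vcount(graph) == 0L)
    return(data.frame(node = character(), degree = integer()))
  d <- igraph::degree(graph)
  out <- data.frame(node = names(d), degree = as.integer(d))
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}
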