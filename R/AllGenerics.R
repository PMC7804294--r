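#' @include AllClasses.R
NULL

#' Kingdom of an object
#' @param x A `ComponentAnnotation` or `RibosomeGraph`.
#' @return Kingdom label (`"A"`, `"B"`, `"E"`, or `"ABE"`).
#' @export
setGeneric("kingdom", function(x) standardGeneric("kingdom"))

#' @rdname kingdom
#' @export
setMethod("kingdom", "ComponentAnnotation", function(x) x@kingdom)

#' @rdname kingdom
#' @export
setMethod("kingdom", "RibosomeGraph", function(x) x@kingdom)

#' Component table of an annotation
#' @param x A `ComponentAnnotation`.
#' @return The component `data.frame` (one row per globular domain,
#'   extension or extra domain).
#' @export
setGeneric("componentTable", function(x) standardGeneric("componentTable"))

#' @rdname componentTable
#' @export
setMethod("componentTable", "ComponentAnnotation", function(x) x@components)

#' Chain-to-molecule map of an annotation
#' @param x A `ComponentAnnotation`.
#' @return `data.frame` mapping structure chains to protein ids or
#'   non-protein molecule types.
#' @export
setGeneric("chainMap", function(x) standardGeneric("chainMap"))

#' @rdname chainMap
#' @export
setMethod("chainMap", "ComponentAnnotation", function(x) x@chainMap)

#' Node table of a network
#' @param x A `RibosomeGraph`.
#' @return `data.frame` of nodes with centre-of-mass coordinates and
#'   functional-module labels.
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "RibosomeGraph", function(x) x@nodes)

#' Aggregated edge table of a network
#' @param x A `RibosomeGraph`.
#' @param includeExcluded Keep tRNA-tRNA / tRNA-mRNA edges that are drawn
#'   but excluded from the statistics?
#' @return `data.frame` of edges (one row per node pair).
#' @export
setGeneric("graphEdges",
           function(x, includeExcluded = TRUE) standardGeneric("graphEdges"))

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "RibosomeGraph", function(x, includeExcluded = TRUE) {
  ed <- x@edges
  if (!includeExcluded && nrow(ed)) ed <- ed[!ed$excluded_from_stats, ]
  ed
})

#' Component-level contact table of a network
#' @param x A `RibosomeGraph`.
#' @param includeExcluded Keep contacts excluded from the statistics?
#' @return `data.frame` with one row per component-level contact.
#' @export
setGeneric("contactTable",
           function(x, includeExcluded = FALSE) standardGeneric("contactTable"))

#' @rdname contactTable
#' @export
setMethod("contactTable", "RibosomeGraph", function(x, includeExcluded = FALSE) {
  ct <- x@contacts
  if (!includeExcluded && nrow(ct)) ct <- ct[!ct$excluded_from_stats, ]
  ct
})

#' Convert a RibosomeGraph to an igraph object
#' @param x A `RibosomeGraph`.
#' @param includeExcluded Keep edges excluded from statistics (they are
#'   still part of the drawn graph and of centrality computations)?
#' @return An undirected \pkg{igraph} graph with node/edge attributes.
#' @export
setGeneric("asIgraph",
           function(x, includeExcluded = TRUE) standardGeneric("asIgraph"))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "RibosomeGraph", function(x, includeExcluded = TRUE) {
  ed <- graphEdges(x, includeExcluded = includeExcluded)
  nd <- graphNodes(x)
  g <- igraph::graph_from_data_frame(
    d = ed[, c("node_a", "node_b",
               setdiff(names(ed), c("node_a", "node_b")))],
    directed = FALSE,
    vertices = nd[, c("node_id", setdiff(names(nd), "node_id"))]
  )
  g
})

#' Columns of a conservation profile
#' @param x A `ConservationProfile`.
#' @return Per-column `data.frame` of conservation values and flags.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname profileTable
#' @export
setMethod("profileTable", "ConservationProfile", function(x) x@columns)

#' @describeIn ComponentAnnotation-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "ComponentAnnotation", function(object) {
  cmp <- object@components
  cat(sprintf("ComponentAnnotation [%s]: %d proteins, %d components (%d extensions)\n",
              object@kingdom, length(unique(cmp$protein_id)), nrow(cmp),
              sum(cmp$component_kind == "extension")))
  invisible(NULL)
})

#' @describeIn RibosomeGraph-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "RibosomeGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  cat(sprintf("RibosomeGraph [%s]: %d nodes (%d proteins, %d functional sites), %d edges (%d contacts)\n",
              object@kingdom, nrow(nd), sum(nd$node_kind == "protein"),
              sum(nd$node_kind == "functional_site"), nrow(ed),
              nrow(object@contacts)))
  invisible(NULL)
})

#' @describeIn ConservationProfile-class Compact display.
#' @param object Object to display.
#' @export
setMethod("show", "ConservationProfile", function(object) {
  cl <- object@columns
  cat(sprintf("ConservationProfile%s: %d columns, %d sequences; %d strict, %d similar (threshold %.0f%%)\n",
              if (nzchar(object@protein_id)) paste0(" [", object@protein_id, "]") else "",
              nrow(cl), object@nSequences, sum(cl$strict), sum(cl$similar),
              100 * object@threshold))
  invisible(NULL)
})
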