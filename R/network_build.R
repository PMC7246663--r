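# Thresholded weighted comorbidity network assembly.

#' Build the thresholded comorbidity network
#'
#' Nodes are the diseases whose prevalence strictly exceeds
#' `minPrevalence`; edges join retained node pairs whose relative risk
#' strictly exceeds `rrThreshold`. Edge weight is the raw co-occurrence
#' count; the relative risk rides along as an annotation. Nodes passing the
#' prevalence filter but gaining no edge are kept as isolates (node and
#' edge criteria are independent). The index disease never appears: it is
#' excluded upstream because every cohort member carries it, which makes
#' its pairwise relative risk identically 1.
#'
#' @param pairStats output of [relativeRisk()].
#' @param prevalence output of [prevalenceTable()] from the same cohort.
#' @param minPrevalence node threshold on prevalence (strict; default 0.01).
#' @param rrThreshold edge threshold on relative risk (strict; default 1.0).
#' @param labels optional named character vector mapping codes to display
#'   labels (defaults to the codes themselves).
#' @return A [ComorbidityNetwork-class]. Raising either threshold never adds
#'   nodes or edges.
#' @export
buildNetwork <- function(pairStats, prevalence, minPrevalence = 0.01,
                         rrThreshold = 1.0, labels = NULL) {
  stopifnot(minPrevalence >= 0, rrThreshold >= 0)
  keep <- prevalence$prevalence > minPrevalence
  nd <- prevalence[keep, c("code", "prevalence"), drop = FALSE]
  nd <- nd[order(nd$code), , drop = FALSE]
  lab <- nd$code
  if (!is.null(labels)) {
    hit <- nd$code %in% names(labels)
    lab[hit] <- unname(labels[nd$code[hit]])
  }
  ed <- pairStats[pairStats$rr > rrThreshold &
                  pairStats$codeA %in% nd$code &
                  pairStats$codeB %in% nd$code,
                  c("codeA", "codeB", "count", "rr"), drop = FALSE]
  ed <- data.frame(from = ed$codeA, to = ed$codeB,
                   weight = as.numeric(ed$count), rr = ed$rr,
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  deg <- table(factor(c(ed$from, ed$to), levels = nd$code))
  nodes <- data.frame(code = nd$code, label = lab,
                      prevalence = nd$prevalence,
                      degree = as.integer(deg[nd$code]),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  new("ComorbidityNetwork", nodes = nodes, edges = ed)
}

#' Accessors for ComorbidityNetwork objects
#'
#' @param x a [ComorbidityNetwork-class].
#' @param ... passed on (unused).
#' @return `nodes()`/`edges()` the underlying data.frames; `nNodes()`,
#'   `nEdges()` counts; `totalEdgeWeight()` the sum of edge weights (m);
#'   `asIgraph()` an [igraph::igraph] with all node/edge attributes.
#' @name ComorbidityNetwork-accessors
#' @aliases nodes edges nNodes nEdges totalEdgeWeight asIgraph
NULL

#' @rdname ComorbidityNetwork-accessors
#' @export
setMethod("nodes", "ComorbidityNetwork", function(x) x@nodes)

#' @rdname ComorbidityNetwork-accessors
#' @export
setMethod("edges", "ComorbidityNetwork", function(x) x@edges)

#' @rdname ComorbidityNetwork-accessors
#' @export
setMethod("nNodes", "ComorbidityNetwork", function(x) nrow(x@nodes))

#' @rdname ComorbidityNetwork-accessors
#' @export
setMethod("nEdges", "ComorbidityNetwork", function(x) nrow(x@edges))

#' @rdname ComorbidityNetwork-accessors
#' @export
setMethod("totalEdgeWeight", "ComorbidityNetwork",
          function(x) sum(x@edges$weight))

#' @rdname ComorbidityNetwork-accessors
#' @export
setMethod("asIgraph", "ComorbidityNetwork", function(x, ...) {
  g <- igraph::graph_from_data_frame(
    x@edges, directed = FALSE,
    vertices = data.frame(name = x@nodes$code, label = x@nodes$label,
                          prevalence = x@nodes$prevalence,
                          degree = x@nodes$degree, stringsAsFactors = FALSE))
  g
})

setMethod("show", "ComorbidityNetwork", function(object) {
  cat("ComorbidityNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (total weight",
      sum(object@edges$weight), ")\n")
  if (nrow(object@nodes)) {
    hub <- object@nodes[which.max(object@nodes$degree), ]
    cat(sprintf("  hub: %s (degree %d); prevalence range %.4f-%.4f\n",
                hub$code, hub$degree, min(object@nodes$prevalence),
                max(object@nodes$prevalence)))
  }
  invisible(NULL)
})

# Construct a network directly from node/edge data.frames (used by importers
# and by tests building toy graphs); applies canonical ordering.
.makeNetwork <- function(nodes, edges) {
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  nodes <- nodes[order(nodes$code), , drop = FALSE]
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$code))
  nodes$degree <- as.integer(deg[nodes$code])
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("ComorbidityNetwork", nodes = nodes, edges = edges)
}

#' Node degree table
#'
#' @param network a [ComorbidityNetwork-class].
#' @return data.frame with columns `code`, `degree` (edge count) and
#'   `weightedDegree` (sum of incident co-occurrence weights), ordered by
#'   degree descending, ties by code.
#' @export
degreeTable <- function(network) {
  stopifnot(is(network, "ComorbidityNetwork"))
  nd <- network@nodes
  wd <- tapply(c(network@edges$weight, network@edges$weight),
               factor(c(network@edges$from, network@edges$to),
                      levels = nd$code), sum)
  wd[is.na(wd)] <- 0
  out <- data.frame(code = nd$code, degree = nd$degree,
                    weightedDegree = as.numeric(wd[nd$code]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}
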