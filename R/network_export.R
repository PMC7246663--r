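# Network export/import: GEXF 1.2 (Gephi), GraphML, delimited edge list.

GEXF_NS <- "http://www.gexf.net/1.2draft"
GEXF_VIZ_NS <- "http://www.gexf.net/1.2draft/viz"

.num <- function(x) sprintf("%.15g", x)

# Degree-bucket colors for the viz hint (light -> dark with rising degree).
.vizColor <- function(degree) {
  br <- stats::quantile(degree, c(1 / 3, 2 / 3), names = FALSE, type = 1)
  bucket <- 1L + (degree > br[1]) + (degree > br[2])
  cols <- rbind(c(198, 219, 239), c(107, 174, 214), c(8, 81, 156))
  cols[bucket, , drop = FALSE]
}

.writeGexf <- function(network, path) {
  nd <- network@nodes
  ed <- network@edges
  doc <- xml2::xml_new_root(
    "gexf", xmlns = GEXF_NS, `xmlns:viz` = GEXF_VIZ_NS, version = "1.2")
  meta <- xml2::xml_add_child(doc, "meta")
  xml2::xml_add_child(meta, "creator", "ComorbidNet")
  xml2::xml_add_child(meta, "description", "comorbidity network")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  attN <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attN, "attribute", id = "0", title = "prevalence",
                      type = "double")
  xml2::xml_add_child(attN, "attribute", id = "1", title = "degree",
                      type = "integer")
  attE <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(attE, "attribute", id = "0", title = "rr",
                      type = "double")
  nodesEl <- xml2::xml_add_child(graph, "nodes")
  col <- if (nrow(nd)) .vizColor(nd$degree) else matrix(0, 0, 3)
  for (i in seq_len(nrow(nd))) {
    nodeEl <- xml2::xml_add_child(nodesEl, "node", id = nd$code[i],
                                  label = nd$label[i])
    av <- xml2::xml_add_child(nodeEl, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = .num(nd$prevalence[i]))
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = as.character(nd$degree[i]))
    # viz hints mirroring the published figure: size ~ prevalence,
    # color bucket ~ degree
    xml2::xml_add_child(nodeEl, "viz:size",
                        value = .num(10 + 40 * nd$prevalence[i]))
    xml2::xml_add_child(nodeEl, "viz:color", r = as.character(col[i, 1]),
                        g = as.character(col[i, 2]),
                        b = as.character(col[i, 3]))
  }
  edgesEl <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(ed))) {
    edgeEl <- xml2::xml_add_child(edgesEl, "edge",
                                  id = as.character(i - 1L),
                                  source = ed$from[i], target = ed$to[i],
                                  weight = .num(ed$weight[i]))
    av <- xml2::xml_add_child(edgeEl, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = .num(ed$rr[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.readGexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = GEXF_NS)
  nodeEls <- xml2::xml_find_all(doc, ".//g:graph/g:nodes/g:node", ns)
  getAtt <- function(el, forId) {
    v <- xml2::xml_attr(xml2::xml_find_first(
      el, sprintf("./g:attvalues/g:attvalue[@for='%s']", forId), ns), "value")
    v
  }
  nodes <- data.frame(
    code = xml2::xml_attr(nodeEls, "id"),
    label = xml2::xml_attr(nodeEls, "label"),
    prevalence = as.numeric(vapply(nodeEls, getAtt, "", forId = "0")),
    degree = as.integer(vapply(nodeEls, getAtt, "", forId = "1")),
    stringsAsFactors = FALSE
  )
  edgeEls <- xml2::xml_find_all(doc, ".//g:graph/g:edges/g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edgeEls, "source"),
    to = xml2::xml_attr(edgeEls, "target"),
    weight = as.numeric(xml2::xml_attr(edgeEls, "weight")),
    rr = as.numeric(vapply(edgeEls, getAtt, "", forId = "0")),
    stringsAsFactors = FALSE
  )
  .makeNetwork(nodes, edges)
}

#' Structurally validate a GEXF 1.2 file
#'
#' Checks conformance with the GEXF 1.2 structure Gephi expects: the
#' `gexf` root in the 1.2draft namespace with `version="1.2"`, a single
#' `graph` element, declared node/edge attributes, node `id`s unique, and
#' every edge `source`/`target` referring to a declared node with a numeric
#' `weight`. (This is a structural conformance check implemented directly;
#' it does not consult the published XSD.)
#'
#' @param path path to a GEXF file.
#' @return `TRUE` (invisibly) if valid; otherwise an error listing every
#'   violated requirement.
#' @export
validateGexf <- function(path) {
  doc <- xml2::read_xml(path)
  probs <- character()
  if (xml2::xml_name(doc) != "gexf")
    probs <- c(probs, "root element must be <gexf>")
  nsuri <- xml2::xml_ns(doc)
  if (!GEXF_NS %in% nsuri)
    probs <- c(probs, paste("missing GEXF 1.2draft namespace", GEXF_NS))
  if (!identical(xml2::xml_attr(doc, "version"), "1.2"))
    probs <- c(probs, "gexf@version must be '1.2'")
  ns <- c(g = GEXF_NS)
  graphs <- xml2::xml_find_all(doc, "./g:graph", ns)
  if (length(graphs) != 1L) {
    probs <- c(probs, "exactly one <graph> element is required")
  } else {
    graph <- graphs[[1]]
    if (!xml2::xml_attr(graph, "defaultedgetype") %in%
        c("undirected", "directed", "mutual", NA))
      probs <- c(probs, "invalid graph@defaultedgetype")
    nodeEls <- xml2::xml_find_all(graph, "./g:nodes/g:node", ns)
    ids <- xml2::xml_attr(nodeEls, "id")
    if (anyNA(ids)) probs <- c(probs, "every <node> must carry an id")
    if (anyDuplicated(ids)) probs <- c(probs, "node ids must be unique")
    declared <- xml2::xml_attr(
      xml2::xml_find_all(graph, "./g:attributes/g:attribute", ns), "id")
    used <- xml2::xml_attr(
      xml2::xml_find_all(graph, ".//g:attvalue", ns), "for")
    if (length(setdiff(used, declared)))
      probs <- c(probs, "attvalue@for refers to an undeclared attribute id")
    edgeEls <- xml2::xml_find_all(graph, "./g:edges/g:edge", ns)
    src <- xml2::xml_attr(edgeEls, "source")
    tgt <- xml2::xml_attr(edgeEls, "target")
    if (anyNA(src) || anyNA(tgt))
      probs <- c(probs, "every <edge> must carry source and target")
    if (length(setdiff(c(src, tgt), ids)))
      probs <- c(probs, "edge endpoints must reference declared node ids")
    w <- xml2::xml_attr(edgeEls, "weight")
    if (any(!is.na(w) & is.na(suppressWarnings(as.numeric(w)))))
      probs <- c(probs, "edge weights must be numeric")
  }
  if (length(probs))
    stop("GEXF validation failed:\n  ", paste(probs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

.edgelistNodePath <- function(path) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", path)
  ext <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", stem)), "", path)
  if (identical(ext, "")) ext <- ".csv"
  paste0(stem, "_nodes", ext)
}

#' Export a comorbidity network
#'
#' Writes the network in a Gephi-readable format. `gexf` produces GEXF 1.2
#' with node attributes (label, prevalence, degree), edge attributes
#' (weight = co-occurrence count, rr), and viz hints (node size
#' proportional to prevalence, color bucket by degree). `graphml` uses
#' igraph's GraphML writer with the same attributes. `edgelist` writes a
#' delimited `from,to,weight,rr` table plus a companion
#' `<stem>_nodes.<ext>` file with node attributes so that the round trip is
#' lossless (including isolated nodes).
#'
#' @param network a [ComorbidityNetwork-class].
#' @param path output file path.
#' @param format `"gexf"`, `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @seealso [importNetwork()], [validateGexf()]
#' @export
exportNetwork <- function(network, path,
                          format = c("gexf", "graphml", "edgelist")) {
  stopifnot(is(network, "ComorbidityNetwork"))
  format <- match.arg(format)
  switch(format,
    gexf = .writeGexf(network, path),
    graphml = {
      igraph::write_graph(asIgraph(network), path, format = "graphml")
      invisible(path)
    },
    edgelist = {
      write.table(network@edges, path, sep = ",", quote = FALSE,
                  row.names = FALSE, eol = "\n")
      write.table(network@nodes, .edgelistNodePath(path), sep = ",",
                  quote = FALSE, row.names = FALSE, eol = "\n")
      invisible(path)
    }
  )
}

#' Import a comorbidity network written by [exportNetwork()]
#'
#' @param path file path (for `edgelist`, the edge file; the companion
#'   `*_nodes` file is read when present, otherwise nodes are reconstructed
#'   from the edges with NA prevalence).
#' @param format `"gexf"`, `"graphml"` or `"edgelist"`.
#' @return A [ComorbidityNetwork-class].
#' @export
importNetwork <- function(path, format = c("gexf", "graphml", "edgelist")) {
  format <- match.arg(format)
  switch(format,
    gexf = .readGexf(path),
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      nodes <- data.frame(
        code = igraph::vertex_attr(g, "name"),
        label = igraph::vertex_attr(g, "label"),
        prevalence = igraph::vertex_attr(g, "prevalence"),
        degree = as.integer(igraph::vertex_attr(g, "degree")),
        stringsAsFactors = FALSE)
      el <- igraph::as_edgelist(g)
      edges <- data.frame(
        from = el[, 1], to = el[, 2],
        weight = if (igraph::ecount(g)) igraph::edge_attr(g, "weight")
                 else numeric(0),
        rr = if (igraph::ecount(g)) igraph::edge_attr(g, "rr")
             else numeric(0),
        stringsAsFactors = FALSE)
      .makeNetwork(nodes, edges)
    },
    edgelist = {
      edges <- read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
      npath <- .edgelistNodePath(path)
      if (file.exists(npath)) {
        nodes <- read.table(npath, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "numeric", "integer"))
      } else {
        codes <- sort(unique(c(edges$from, edges$to)))
        nodes <- data.frame(code = codes, label = codes,
                            prevalence = NA_real_, degree = 0L,
                            stringsAsFactors = FALSE)
      }
      .makeNetwork(nodes, edges)
    }
  )
}
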