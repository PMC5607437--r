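# Term co-occurrence network: nodes are terms, edges join terms that
# appeared in the same search, weighted by the number of such searches.

#' Build the term co-occurrence graph
#'
#' For every search, duplicate tokens collapse first; each unordered pair
#' of distinct terms in the search then increments that edge's weight by
#' one. Terms in `exclude` are dropped before pairing (used to remove
#' hub terms that would overshadow the rest of the graph). Single-term
#' searches contribute an isolated node. The result does not depend on
#' the order in which searches are processed.
#'
#' @param cleaned A `cleaned_searches` object or long token data frame
#'   with `search_id` and `token` columns.
#' @param exclude Character vector of terms to drop before pairing.
#' @return An object of class `cooccurrence_graph`: list with `nodes`
#'   (data frame `term`, `frequency` = token instances, `degree` =
#'   distinct neighbours) and `edges` (data frame `term1`, `term2`,
#'   `weight`, with `term1 < term2`).
#' @export
cooccurrence_graph <- function(cleaned, exclude = character(0)) {
  tok <- if (inherits(cleaned, "cleaned_searches")) cleaned$tokens else cleaned
  keep <- !tok$token %in% exclude & nzchar(tok$token)
  tok <- tok[keep, , drop = FALSE]
  freq_tab <- table(tok$token)
  by_search <- split(tok$token, tok$search_id)
  by_search <- lapply(by_search, unique)
  pair_list <- lapply(by_search, function(terms) {
    if (length(terms) < 2L) return(NULL)
    terms <- sort(terms)
    cmb <- utils::combn(terms, 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\x1f")
  })
  pairs <- unlist(pair_list, use.names = FALSE)
  if (length(pairs)) {
    wt <- table(pairs)
    sp <- strsplit(names(wt), "\x1f", fixed = TRUE)
    edges <- data.frame(
      term1 = vapply(sp, `[[`, "", 1L),
      term2 = vapply(sp, `[[`, "", 2L),
      weight = as.numeric(wt),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$term1, edges$term2), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(term1 = character(0), term2 = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  terms <- sort(names(freq_tab))
  degree <- table(factor(c(edges$term1, edges$term2), levels = terms))
  nodes <- data.frame(term = terms,
                      frequency = as.numeric(freq_tab[terms]),
                      degree = as.numeric(degree),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat("<cooccurrence_graph> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence graph to an igraph object
#'
#' @param graph A `cooccurrence_graph`.
#' @return An undirected weighted `igraph` graph (requires the igraph
#'   package).
#' @export
cooccurrence_igraph <- function(graph) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for cooccurrence_igraph()")
  igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$term1, to = graph$edges$term2,
                   weight = graph$edges$weight),
    directed = FALSE,
    vertices = graph$nodes
  )
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Export a co-occurrence graph
#'
#' Writes three files under `path` (a stem): `<stem>_nodes.tsv` (term,
#' frequency, degree), `<stem>_edges.tsv` (term1, term2, weight) and
#' `<stem>.gexf` (GEXF 1.2, suitable for external network-visualization
#' software, with frequency and degree node attributes and edge
#' weights). The TSV pair round-trips losslessly via
#' [read_graph_exports()].
#'
#' @param graph A `cooccurrence_graph`.
#' @param path Output stem (no extension).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "cooccurrence_graph"))
  nodes_path <- paste0(path, "_nodes.tsv")
  edges_path <- paste0(path, "_edges.tsv")
  gexf_path <- paste0(path, ".gexf")
  utils::write.table(graph$nodes, nodes_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(graph$edges, edges_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  n <- graph$nodes
  e <- graph$edges
  node_xml <- sprintf(
    paste0('      <node id="%s" label="%s">\n',
           '        <attvalues><attvalue for="0" value="%s"/>',
           '<attvalue for="1" value="%s"/></attvalues>\n',
           '      </node>'),
    .xml_escape(n$term), .xml_escape(n$term),
    format(n$frequency, trim = TRUE, scientific = FALSE),
    format(n$degree, trim = TRUE, scientific = FALSE))
  edge_xml <- if (nrow(e)) sprintf(
    '      <edge id="%d" source="%s" target="%s" weight="%s"/>',
    seq_len(nrow(e)) - 1L, .xml_escape(e$term1), .xml_escape(e$term2),
    format(e$weight, trim = TRUE, scientific = FALSE)) else character(0)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="frequency" type="double"/>',
    '      <attribute id="1" title="degree" type="double"/>',
    '    </attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>',
    '</gexf>')
  ok <- tryCatch({ writeLines(xml, gexf_path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write graph export to ", gexf_path)
  invisible(c(nodes = nodes_path, edges = edges_path, gexf = gexf_path))
}

#' Read back a TSV graph export
#'
#' @param path The stem used in [export_graph()].
#' @return A `cooccurrence_graph`.
#' @export
read_graph_exports <- function(path) {
  nodes <- utils::read.delim(paste0(path, "_nodes.tsv"),
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(path, "_edges.tsv"),
                             stringsAsFactors = FALSE)
  nodes$term <- as.character(nodes$term)
  nodes$frequency <- as.numeric(nodes$frequency)
  nodes$degree <- as.numeric(nodes$degree)
  edges$term1 <- as.character(edges$term1)
  edges$term2 <- as.character(edges$term2)
  edges$weight <- as.numeric(edges$weight)
  structure(list(nodes = nodes, edges = edges),
            class = "cooccurrence_graph")
}
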