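## SIF and GraphML export of species-reaction graphs (the Cytoscape
## hand-off formats), plus a GraphML reader for round-trip checks.

#' Export a graph as SIF or GraphML
#'
#' SIF uses one line per edge, `source<TAB>kind<TAB>target`, so the edge
#' word carries the edge kind (reactant/product/modifier).  GraphML
#' preserves node kind and label and edge kind as attributes.
#'
#' @param graph An [directed_graph()].
#' @param format `"SIF"` or `"GraphML"`.
#' @param file Path, or `NULL` to return the document as a character
#'   string.
#' @return The path (invisibly) or the document text.
#' @export
export_network <- function(graph, format = c("SIF", "GraphML"),
                           file = NULL) {
  stopifnot(inherits(graph, "fn_graph"))
  format <- match.arg(format)
  if (format == "SIF") {
    txt <- paste(graph$edges$from, graph$edges$kind, graph$edges$to,
                 sep = "\t")
    ## isolated-in-graph nodes (none in valid reaction graphs, but SIF
    ## convention lists them as bare names)
    connected <- unique(c(graph$edges$from, graph$edges$to))
    txt <- c(txt, setdiff(graph$nodes$id, connected))
    txt <- paste(txt, collapse = "\n")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    out <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">"),
      "  <key id=\"kind\" for=\"node\" attr.name=\"kind\" attr.type=\"string\"/>",
      "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
      "  <key id=\"ekind\" for=\"edge\" attr.name=\"kind\" attr.type=\"string\"/>",
      "  <graph id=\"G\" edgedefault=\"directed\">")
    for (i in seq_len(nrow(graph$nodes)))
      out <- c(out, sprintf(
        "    <node id=\"%s\"><data key=\"kind\">%s</data><data key=\"label\">%s</data></node>",
        graph$nodes$id[i], graph$nodes$kind[i], esc(graph$nodes$label[i])))
    for (i in seq_len(nrow(graph$edges)))
      out <- c(out, sprintf(
        "    <edge source=\"%s\" target=\"%s\"><data key=\"ekind\">%s</data></edge>",
        graph$edges$from[i], graph$edges$to[i], graph$edges$kind[i]))
    out <- c(out, "  </graph>", "</graphml>")
    txt <- paste(out, collapse = "\n")
  }
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Read a GraphML document written by [export_network()]
#'
#' @param source Path or literal GraphML string.
#' @return An [directed_graph()].
#' @export
read_graphml <- function(source) {
  doc <- xml2::read_xml(source)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  nodes <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_data <- function(nd, key) {
    v <- xml2::xml_text(xml2::xml_find_first(
      nd, sprintf("./g:data[@key='%s']", key), ns))
    v
  }
  ndf <- data.frame(
    id = xml2::xml_attr(nodes, "id"),
    kind = vapply(nodes, get_data, "", key = "kind"),
    label = vapply(nodes, get_data, "", key = "label"),
    stringsAsFactors = FALSE)
  edges <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edf <- data.frame(
    from = xml2::xml_attr(edges, "source"),
    to = xml2::xml_attr(edges, "target"),
    kind = vapply(edges, get_data, "", key = "ekind"),
    stringsAsFactors = FALSE)
  directed_graph(ndf, edf)
}
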