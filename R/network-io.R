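#' Convert a ceRNA network to an igraph graph
#'
#' Node attributes `class` and `direction` are carried over; edge
#' attribute `type` distinguishes the two tripartite edge kinds.
#'
#' @param net `cerna_network`.
#' @return undirected [igraph::igraph] graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cerna_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Export a ceRNA network for external viewers
#'
#' Formats: `"sif"` (Cytoscape simple interaction format, rows
#' `source<TAB>relation<TAB>target` with relation `lncRNA_miRNA` or
#' `miRNA_mRNA`), `"graphml"` (carries node `class` and `direction`
#' attributes; round-trips through [read_network_graphml()]), or
#' `"tsv"` (headered edge list).
#'
#' @param net `cerna_network`.
#' @param path output file.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "cerna_network"))
  if (!is.character(format) ||
      !all(format %in% c("sif", "graphml", "tsv")) || length(format) < 1L)
    stop("unknown network format: ", paste(format, collapse = ", "),
         call. = FALSE)
  format <- match.arg(format)
  validate_cerna_network(net)
  if (format == "sif") {
    lines <- with(net$edges, paste(from, type, to, sep = "\t"))
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!nrow(net$nodes)) {
      # igraph writes no attribute schema for an empty graph; emit a
      # minimal well-formed GraphML document instead
      writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
                   '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
                   '  <graph edgedefault="undirected"/>',
                   '</graphml>'), path)
    } else {
      igraph::write_graph(as_igraph(net), path, format = "graphml")
    }
  }
  invisible(path)
}

#' Read back a SIF export
#'
#' @param path SIF file.
#' @return data.frame with columns from, type, to.
#' @export
read_network_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(from = character(), type = character(),
                      to = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed SIF line in ", path, call. = FALSE)
  data.frame(from = vapply(parts, `[[`, "", 1L),
             type = vapply(parts, `[[`, "", 2L),
             to = vapply(parts, `[[`, "", 3L), stringsAsFactors = FALSE)
}

#' Read back a GraphML export
#'
#' @param path GraphML file.
#' @return list with `nodes` (id, class, direction where present) and
#'   `edges` (from, to, type) data.frames.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!igraph::vcount(g))
    return(list(nodes = data.frame(id = character(), class = character(),
                                   direction = character(),
                                   stringsAsFactors = FALSE),
                edges = data.frame(from = character(), to = character(),
                                   type = character(),
                                   stringsAsFactors = FALSE)))
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(id = va$name, stringsAsFactors = FALSE)
  for (a in intersect(c("class", "direction"), names(va)))
    nodes[[a]] <- va[[a]]
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L],
                      stringsAsFactors = FALSE)
  ea <- igraph::edge_attr(g)
  if ("type" %in% names(ea)) edges$type <- ea$type
  list(nodes = nodes[order(nodes$id), , drop = FALSE],
       edges = edges[order(edges$from, edges$to), , drop = FALSE])
}

#' Write the triplet evidence table
#'
#' @param triplets `cerna_triplets`.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_triplets <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
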