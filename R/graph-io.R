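ddsn_formats <- c("gexf", "graphml", "edgelist")

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gexf = "gexf",
    graphml = "graphml",
    tsv = "edgelist", txt = "edgelist", edgelist = "edgelist",
    abort(paste0("cannot guess graph format from extension '.", ext,
                 "'; pass `format` explicitly"))
  )
}

#' Write a DDSN to GEXF, GraphML or a weighted edge list
#'
#' Integer edge weights are preserved exactly in all three formats.  GEXF
#' and GraphML additionally carry node attributes (drug name, community id,
#' centralities) and, for GEXF, layout coordinates as `viz:position`, so the
#' files open directly in Gephi.  The 3-column edge list (`from`, `to`,
#' `weight`) has nowhere to record isolated nodes and drops them.
#'
#' @param g A `ddsn` graph.
#' @param path Output file path.
#' @param format One of `"gexf"`, `"graphml"`, `"edgelist"`; guessed from
#'   the file extension when omitted.
#' @return `path`, invisibly.
#' @export
write_ddsn <- function(g, path, format = NULL) {
  stopifnot(inherits(g, "igraph"))
  if (is.null(format)) format <- guess_format(path)
  if (!format %in% ddsn_formats) {
    abort(paste0("unsupported graph format: ", format))
  }
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    edgelist = readr::write_tsv(tidy.ddsn(as_ddsn(g)), path,
                                progress = FALSE),
    gexf = write_gexf(g, path)
  )
  invisible(path)
}

#' Read a DDSN written by [write_ddsn()]
#'
#' @param path Input file path.
#' @param format One of `"gexf"`, `"graphml"`, `"edgelist"`; guessed from
#'   the file extension when omitted.
#' @return A `ddsn` graph.
#' @export
read_ddsn <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("graph file not found: ", path))
  if (is.null(format)) format <- guess_format(path)
  if (!format %in% ddsn_formats) {
    abort(paste0("unsupported graph format: ", format))
  }
  g <- switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    edgelist = {
      edges <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
      igraph::graph_from_data_frame(edges, directed = FALSE)
    },
    gexf = read_gexf(path)
  )
  as_ddsn(g)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# GEXF 1.2draft writer. Numeric vertex attributes (community, centralities)
# become attvalues; x/y become viz:position nodes.
write_gexf <- function(g, path) {
  vattrs <- setdiff(igraph::vertex_attr_names(g), c("name", "x", "y"))
  has_viz <- all(c("x", "y") %in% igraph::vertex_attr_names(g))
  attr_type <- function(a) {
    v <- igraph::vertex_attr(g, a)
    if (is.integer(v)) "integer" else if (is.numeric(v)) "double" else "string"
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<gexf xmlns="http://www.gexf.net/1.2draft" ',
           'xmlns:viz="http://www.gexf.net/1.2draft/viz" version="1.2">'),
    '  <graph mode="static" defaultedgetype="undirected">'
  )
  if (length(vattrs) > 0) {
    lines <- c(lines, '    <attributes class="node">',
               vapply(seq_along(vattrs), function(i) {
                 sprintf('      <attribute id="%d" title="%s" type="%s"/>',
                         i - 1L, xml_escape(vattrs[i]),
                         attr_type(vattrs[i]))
               }, character(1)),
               '    </attributes>')
  }
  lines <- c(lines, "    <nodes>")
  nm <- igraph::V(g)$name
  for (i in seq_len(igraph::vcount(g))) {
    open <- sprintf('      <node id="%s" label="%s">',
                    xml_escape(nm[i]), xml_escape(nm[i]))
    body <- character(0)
    if (length(vattrs) > 0) {
      body <- c("        <attvalues>",
                vapply(seq_along(vattrs), function(j) {
                  v <- igraph::vertex_attr(g, vattrs[j])[i]
                  sprintf('          <attvalue for="%d" value="%s"/>',
                          j - 1L, xml_escape(format(v, digits = 17)))
                }, character(1)),
                "        </attvalues>")
    }
    if (has_viz) {
      body <- c(body, sprintf(
        '        <viz:position x="%s" y="%s" z="0"/>',
        format(igraph::V(g)$x[i], digits = 17),
        format(igraph::V(g)$y[i], digits = 17)
      ))
    }
    lines <- c(lines, open, body, "      </node>")
  }
  lines <- c(lines, "    </nodes>", "    <edges>")
  if (igraph::ecount(g) > 0) {
    ends <- igraph::as_edgelist(g)
    w <- edge_weights(g)
    lines <- c(lines, sprintf(
      '      <edge id="%d" source="%s" target="%s" weight="%s"/>',
      seq_len(nrow(ends)) - 1L, xml_escape(ends[, 1]),
      xml_escape(ends[, 2]), format(w, digits = 17)
    ))
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = xml2::xml_ns(doc)[["d1"]])
  node_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- tibble(name = xml2::xml_attr(node_xml, "id"))
  attrs <- xml2::xml_find_all(doc, ".//g:attribute", ns)
  attr_title <- setNames(xml2::xml_attr(attrs, "title"),
                         xml2::xml_attr(attrs, "id"))
  attr_type <- setNames(xml2::xml_attr(attrs, "type"),
                        xml2::xml_attr(attrs, "id"))
  for (id in names(attr_title)) {
    vals <- vapply(node_xml, function(nd) {
      av <- xml2::xml_find_first(
        nd, sprintf(".//g:attvalue[@for='%s']", id), ns)
      xml2::xml_attr(av, "value")
    }, character(1))
    nodes[[attr_title[[id]]]] <-
      if (attr_type[[id]] %in% c("integer", "long")) as.integer(vals)
      else if (attr_type[[id]] %in% c("double", "float")) as.numeric(vals)
      else vals
  }
  pos <- xml2::xml_find_first(node_xml[1], ".//viz:position",
                              xml2::xml_ns(doc))
  if (length(node_xml) > 0 && !inherits(pos, "xml_missing")) {
    get_pos <- function(axis) {
      vapply(node_xml, function(nd) {
        as.numeric(xml2::xml_attr(
          xml2::xml_find_first(nd, ".//viz:position", xml2::xml_ns(doc)),
          axis))
      }, numeric(1))
    }
    nodes$x <- get_pos("x")
    nodes$y <- get_pos("y")
  }
  edge_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- tibble(
    from = xml2::xml_attr(edge_xml, "source"),
    to = xml2::xml_attr(edge_xml, "target"),
    weight = as.numeric(xml2::xml_attr(edge_xml, "weight"))
  )
  edges$weight[is.na(edges$weight)] <- 1
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
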