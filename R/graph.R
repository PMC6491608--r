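#' Build the subunit connectivity graph
#'
#' Undirected graph with one node per subunit (positioned at the
#' barycenter, sized by physical volume) and one edge per touching pair,
#' weighted by the ratio of the contact surface to the mean total surface
#' of the pair. Duplicate `(i, j)`/`(j, i)` edges collapse onto one
#' undirected edge.
#'
#' @param records `data.frame` from [subunit_volumes()].
#' @param edges `data.frame` from [contact_surfaces()].
#' @return an [igraph::make_graph] object with vertex attributes `name`
#'   (label), `voxel_count`, `volume_mm3`, `bx`, `by`, `bz` and edge
#'   attributes `face_count`, `area_mm2`, `weight`.
#' @export
build_graph <- function(records, edges) {
  if (!all(c(edges$label_i, edges$label_j) %in% records$label))
    lob_stop("edge endpoints must all be present in records",
             "lobuseg_consistency_error")
  verts <- data.frame(name = as.character(records$label),
                      label = records$label,
                      voxel_count = records$voxel_count,
                      volume_mm3 = records$volume_mm3,
                      bx = records$bx, by = records$by, bz = records$bz)
  if (nrow(edges)) {
    lo <- pmin(edges$label_i, edges$label_j)
    hi <- pmax(edges$label_i, edges$label_j)
    key <- paste(lo, hi)
    keep <- !duplicated(key)
    ed <- data.frame(from = as.character(lo[keep]), to = as.character(hi[keep]),
                     face_count = edges$face_count[keep],
                     area_mm2 = edges$area_mm2[keep],
                     weight = edges$weight[keep])
  } else {
    ed <- data.frame(from = character(), to = character())
  }
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' Partition the subunit graph into clusters of well-connected subunits
#'
#' Operationalizes the visual identification of macro-domains: with
#' `method = "threshold"` (default), clusters are the connected components
#' of the subgraph retaining edges whose weight is at least
#' `weight_threshold`; singletons are reported as their own clusters.
#' `method = "modularity"` instead applies greedy modularity community
#' detection on the weighted graph (the threshold is then ignored).
#'
#' @param graph a [build_graph()] result.
#' @param weight_threshold edge weight cut-off in `[0, 1]`.
#' @param method `"threshold"` or `"modularity"`.
#' @return `data.frame` with columns `label` and `cluster`, with the
#'   threshold recorded in attribute `"weight_threshold"`.
#' @export
partition_clusters <- function(graph, weight_threshold = 0.05,
                               method = c("threshold", "modularity")) {
  method <- match.arg(method)
  if (method == "threshold") {
    if (weight_threshold < 0 || weight_threshold > 1)
      lob_stop("weight_threshold must be in [0, 1]", "lobuseg_param_error")
    keep <- igraph::E(graph)[igraph::E(graph)$weight >= weight_threshold]
    sub <- igraph::subgraph_from_edges(graph, keep, delete.vertices = FALSE)
    comp <- igraph::components(sub)$membership
  } else {
    comp <- igraph::membership(igraph::cluster_fast_greedy(graph))
  }
  out <- data.frame(label = as.integer(igraph::V(graph)$name),
                    cluster = as.integer(comp))
  out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "weight_threshold") <-
    if (method == "threshold") weight_threshold else NA_real_
  attr(out, "method") <- method
  out
}

#' Export / import the subunit graph
#'
#' GraphML (via igraph) or a JSON node-link document (nodes and links with
#' all attributes, written with full numeric precision). A graph exported
#' to either format and re-imported with [import_graph()] reproduces the
#' node and edge sets and their attributes.
#'
#' @param graph a [build_graph()] result.
#' @param path output file.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly (for `export_graph`); an igraph object (for
#'   `import_graph`).
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  if (length(format) == 1 && !format %in% c("graphml", "json"))
    lob_stop(sprintf("unknown graph format '%s'", format), "lobuseg_param_error")
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- igraph::as_data_frame(graph, what = "vertices")
    links <- igraph::as_data_frame(graph, what = "edges")
    jsonlite::write_json(list(directed = FALSE, nodes = nodes, links = links),
                         path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  if (length(format) == 1 && !format %in% c("graphml", "json"))
    lob_stop(sprintf("unknown graph format '%s'", format), "lobuseg_param_error")
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if ("id" %in% igraph::vertex_attr_names(g))
      g <- igraph::delete_vertex_attr(g, "id")
    return(g)
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(doc$nodes)
  links <- as.data.frame(doc$links)
  if (!nrow(links)) links <- data.frame(from = character(), to = character())
  igraph::graph_from_data_frame(links, directed = FALSE, vertices = nodes)
}
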