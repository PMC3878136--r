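# Structure-relationship graph: structures and supramolecular constructs as
# nodes, covering containment relations as edges, with the strict vertical
# hierarchy 0D SCs < 1D SCs < 2D SCs < 3D SCs < crystal structures.

#' Build the structure-relationship graph
#'
#' Nodes are crystal structures (level 4) and SCs (level = dimensionality);
#' directed edges run from each SC to the SCs/structures that contain it,
#' keeping only covering relations (transitive edges removed). An SC with
#' fewer than two member structures is rejected.
#'
#' @param scs An `sc_set` from [compare_family()].
#' @param structures Character vector of structure ids to include as nodes;
#'   defaults to the union of SC members.
#' @return Object of class `relationship_graph`: `nodes` tibble (`id`,
#'   `type`, `level`), `edges` tibble (`from`, `to`), and the underlying
#'   igraph object in `$graph`.
#' @export
build_graph <- function(scs, structures = NULL) {
  bad <- scs$sc_id[scs$n_members < 2]
  if (length(bad)) {
    stop("SC(s) with fewer than 2 member structures: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structures <- sort(unique(structures %||% unlist(scs$members)))
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = scs$sc_id, type = "sc",
                   level = as.numeric(scs$dimensionality)),
    tibble::tibble(id = structures, type = "structure", level = 4))
  nodes <- dplyr::arrange(nodes, .data$level, .data$id)
  # full relation: SC -> containing SC (from depends_on, reversed), and
  # SC -> member structure
  rel <- list()
  for (i in seq_len(nrow(scs))) {
    for (dep in scs$depends_on[[i]]) {
      rel[[length(rel) + 1L]] <- c(from = dep, to = scs$sc_id[i])
    }
    for (mem in scs$members[[i]]) {
      rel[[length(rel) + 1L]] <- c(from = scs$sc_id[i], to = mem)
    }
  }
  edges <- if (length(rel)) {
    unique(tibble::as_tibble(do.call(rbind, rel)))
  } else {
    tibble::tibble(from = character(0), to = character(0))
  }
  # transitive (covering) reduction on the relation DAG
  if (nrow(edges) > 1) {
    g_full <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                            vertices = nodes$id)
    reach <- igraph::distances(g_full, mode = "out")
    keep <- vapply(seq_len(nrow(edges)), function(k) {
      u <- edges$from[k]; v <- edges$to[k]
      mids <- setdiff(nodes$id[is.finite(reach[u, ]) & reach[u, ] > 0], v)
      !any(is.finite(reach[mids, v]) & reach[mids, v] > 0)
    }, logical(1))
    edges <- edges[keep, ]
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  lev <- stats::setNames(nodes$level, nodes$id)
  if (any(lev[edges$from] >= lev[edges$to])) {
    stop("internal error: edge violates the level hierarchy", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "relationship_graph")
}

#' @export
print.relationship_graph <- function(x, ...) {
  cat(sprintf("<relationship_graph> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Upward closure of a node
#'
#' All nodes reachable by following containment upwards -- for an SC, every
#' SC and crystal structure that contains it.
#'
#' @param graph A [build_graph()] result.
#' @param node Node id.
#' @return Character vector of ancestor node ids (excluding the node itself).
#' @export
ancestors_of <- function(graph, node) {
  if (!node %in% graph$nodes$id) stop("unknown node id: ", node, call. = FALSE)
  r <- igraph::subcomponent(graph$graph, node, mode = "out")
  setdiff(sort(names(r)), node)
}

descendants_of <- function(graph, node) {
  if (!node %in% graph$nodes$id) stop("unknown node id: ", node, call. = FALSE)
  r <- igraph::subcomponent(graph$graph, node, mode = "in")
  setdiff(sort(names(r)), node)
}

#' Highest common constructs of two structures
#'
#' Follows the branches radiating downwards from two structure nodes until
#' they meet: returns the maximal (highest-level) SCs common to both, i.e.
#' the common descendants not contained in any other common descendant.
#'
#' @param graph A [build_graph()] result.
#' @param node_a,node_b Structure (or SC) node ids.
#' @return Character vector of SC node ids; empty when the structures share
#'   no construct.
#' @export
common_constructs <- function(graph, node_a, node_b) {
  common <- intersect(descendants_of(graph, node_a),
                      descendants_of(graph, node_b))
  if (length(common) == 0) return(character(0))
  keep <- vapply(common, function(u) {
    !any(ancestors_of(graph, u) %in% common)
  }, logical(1))
  sort(common[keep])
}

#' Serialize a relationship graph to DOT
#'
#' Deterministic, byte-stable DOT text with one `rank=same` group per level
#' (0D at the bottom, structures at the top).
#'
#' @param graph A [build_graph()] result.
#' @return Character vector of DOT lines.
#' @export
to_dot <- function(graph) {
  q <- function(x) paste0("\"", x, "\"")
  lines <- c("digraph relationships {", "  rankdir=BT;")
  for (lv in sort(unique(graph$nodes$level))) {
    ids <- sort(graph$nodes$id[graph$nodes$level == lv])
    shape <- if (lv == 4) "box" else "ellipse"
    lines <- c(lines,
               sprintf("  { rank=same; %s }",
                       paste(vapply(ids, function(i) {
                         sprintf("%s [shape=%s];", q(i), shape)
                       }, character(1)), collapse = " ")))
  }
  ed <- graph$edges[order(graph$edges$from, graph$edges$to), ]
  lines <- c(lines,
             sprintf("  %s -> %s;", q(ed$from), q(ed$to)),
             "}")
  lines
}

#' Serialize a relationship graph to JSON adjacency form
#'
#' @param graph A [build_graph()] result.
#' @return A JSON string with `nodes` (id, type, level) and `edges`
#'   (from, to).
#' @export
graph_to_json <- function(graph) {
  jsonlite::toJSON(list(nodes = graph$nodes, edges = graph$edges),
                   dataframe = "rows", auto_unbox = TRUE, digits = NA)
}
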