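# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cluster match
#'
#' @param x A [match_clusters()] result.
#' @param ... Unused.
#' @return The matched-pair tibble without attributes.
#' @export
tidy.cluster_match <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a cluster match
#'
#' @param x A [match_clusters()] result.
#' @param ... Unused.
#' @return Tibble with `n_matched`, `n_translation`, `n_improper`,
#'   `dissimilarity`.
#' @export
glance.cluster_match <- function(x, ...) {
  tibble::tibble(
    n_matched = nrow(x),
    n_translation = sum(x$translation),
    n_improper = sum(x$improper),
    dissimilarity = if (nrow(x)) dissimilarity_index(x) else NA_real_)
}

#' Tidy a packing comparison
#'
#' @param x A [compare_structures()] result.
#' @param ... Unused.
#' @return The matched-pair tibble.
#' @export
tidy.packing_comparison <- function(x, ...) tidy(x$match)

#' One-row summary of a packing comparison
#'
#' @param x A [compare_structures()] result.
#' @param ... Unused.
#' @return Tibble with ids, matched count, dimensionality, base magnitudes
#'   and dissimilarity.
#' @export
glance.packing_comparison <- function(x, ...) {
  tibble::tibble(
    id_a = x$id_a, id_b = x$id_b, n_matched = nrow(x$match),
    dimensionality = if (is.null(x$motif)) NA_integer_ else
      x$motif$dimensionality,
    base_magnitudes = list(if (is.null(x$motif)) numeric(0) else
      sort(x$motif$magnitudes)),
    dissimilarity = x$dissimilarity)
}

#' Tidy an SC set
#'
#' @param x An `sc_set` from [compare_family()].
#' @param ... Unused.
#' @return The flat SC table, see [sc_table()].
#' @export
tidy.sc_set <- function(x, ...) sc_table(x)

#' Plot a relationship graph
#'
#' Layered layout: 0D constructs at the bottom, structures at the top,
#' lexicographic order within a level.
#'
#' @param object A [build_graph()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relationship_graph <- function(object, ...) {
  nodes <- object$nodes
  nodes <- dplyr::arrange(nodes, .data$level, .data$id)
  nodes <- dplyr::mutate(dplyr::group_by(nodes, .data$level),
                         x = seq_along(.data$id) -
                           (dplyr::n() + 1) / 2)
  nodes <- dplyr::ungroup(nodes)
  ed <- object$edges
  ed$x <- nodes$x[match(ed$from, nodes$id)]
  ed$y <- nodes$level[match(ed$from, nodes$id)]
  ed$xend <- nodes$x[match(ed$to, nodes$id)]
  ed$yend <- nodes$level[match(ed$to, nodes$id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$level,
                                     label = .data$id,
                                     fill = .data$type)) +
    ggplot2::scale_y_continuous(
      breaks = 0:4, labels = c("0D", "1D", "2D", "3D", "structures")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   panel.grid.minor = ggplot2::element_blank())
}

#' Plot a cluster fingerprint
#'
#' @param object A [build_cluster()] result.
#' @param ... Unused.
#' @return A ggplot object showing the shell centroid-distance multiset by
#'   provenance class.
#' @export
autoplot.cluster <- function(object, ...) {
  fp <- cluster_fingerprint(object)
  ggplot2::ggplot(fp, ggplot2::aes(x = .data$dist, y = 0,
                                   colour = .data$prov_class)) +
    ggplot2::geom_point(size = 3, alpha = 0.8,
                        position = ggplot2::position_jitter(height = 0.05,
                                                            seed = 1)) +
    ggplot2::labs(x = "shell centroid distance (Å)", y = NULL,
                  colour = "provenance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
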