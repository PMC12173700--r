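#' Volcano-style view of an edge-wise contrast
#'
#' Rosenthal effect size against `-log10` parametric p per tested edge,
#' with candidate (and, when available, permutation-significant) edges
#' highlighted and the candidate threshold drawn.
#'
#' @param object A `contrast_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contrast_result <- function(object, ...) {
  st <- dplyr::filter(object$stats, .data$tested)
  sig <- if ("significant" %in% names(st)) st$significant %in% TRUE else
    rep(FALSE, nrow(st))
  st$status <- dplyr::case_when(
    sig ~ "significant",
    st$candidate ~ "candidate",
    TRUE ~ "background")
  ggplot2::ggplot(st, ggplot2::aes(x = .data$r_effect,
                                   y = -log10(pmax(.data$p_param, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(background = "grey60",
                                            candidate = "steelblue",
                                            significant = "firebrick")) +
    ggplot2::labs(x = "Rosenthal r", y = expression(-log[10]~p),
                  colour = NULL,
                  title = sprintf("Edge-wise contrast (%s)", object$modality)) +
    ggplot2::theme_minimal()
}

#' Node-level view of the overlap test
#'
#' BH-adjusted q per observed intersect node, with the significance cut.
#'
#' @param object An `overlap_result`.
#' @param q_crit Reference line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_result <- function(object, q_crit = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$node <- factor(df$node_id, levels = df$node_id[order(df$q)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$q,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = q_crit, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "intersect node", y = "BH q", fill = "significant",
                  title = "Structural-functional overlap nodes") +
    ggplot2::theme_minimal()
}

#' Plot a difference-graph subnetwork
#'
#' Force-directed layout of one extracted subnetwork; node size scales with
#' eigenvector centrality, hubs are highlighted, edge colour encodes
#' direction (hyper/hypo-connectivity in the case group).
#'
#' @param subnetworks Output of [extract_subnetworks()].
#' @param which Subnetwork index (1 = largest).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_subnetwork <- function(subnetworks, which = 1, seed = 1L) {
  comps <- attr(subnetworks, "components")
  if (which > length(comps)) stop("no subnetwork ", which, call. = FALSE)
  s <- comps[[which]]
  meta <- subnetworks[subnetworks$subnetwork == which, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(s$edges$i), to = as.character(s$edges$j)),
    directed = FALSE, vertices = data.frame(name = as.character(s$nodes)))
  xy <- withr_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(node_id = s$nodes, x = xy[, 1], y = xy[, 2])
  nodes <- dplyr::left_join(nodes, meta, by = "node_id")
  edges <- dplyr::left_join(
    dplyr::left_join(s$edges,
                     dplyr::rename(nodes[, c("node_id", "x", "y")],
                                   i = "node_id", x0 = "x", y0 = "y"),
                     by = "i"),
    dplyr::rename(nodes[, c("node_id", "x", "y")],
                  j = "node_id", x1 = "x", y1 = "y"),
    by = "j")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$direction)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$centrality,
                                     shape = .data$is_hub)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node_id),
                       vjust = -1, size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(title = sprintf("Subnetwork %d (%d nodes, %d edges)",
                                  which, s$size, s$edge_count),
                  colour = "direction", shape = "hub") +
    ggplot2::theme_void()
}
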