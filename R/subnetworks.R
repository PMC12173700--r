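#' Difference graph of significant edges
#'
#' The sparse graph whose edges differ significantly between groups: one row
#' per significant edge of a completed contrast (falling back to the
#' candidate edges if the permutation stage has not run), with direction and
#' Rosenthal effect size.
#'
#' @param contrast A `contrast_result`.
#' @return A tibble with columns `i`, `j`, `direction`, `r_effect`, plus
#'   attribute `n_parcels`.
#' @export
difference_graph <- function(contrast) {
  st <- contrast$stats
  keep <- if ("significant" %in% names(st)) st$significant else st$candidate
  out <- dplyr::select(st[keep, ], "i", "j", "direction", "r_effect")
  attr(out, "n_parcels") <- contrast$n_parcels
  out
}

#' Connected components of a difference graph
#'
#' Undirected components, sorted the way subnetworks are reported: by node
#' count descending, ties broken by edge count descending, then by smallest
#' member node id ascending.
#'
#' @param graph An edge tibble with columns `i`, `j` (as from
#'   [difference_graph()]).
#' @return A list of subnetworks, each a list with `nodes` (sorted integer
#'   vector), `edges` (tibble), `size`, `edge_count`.
#' @export
connected_components <- function(graph) {
  if (nrow(graph) == 0) return(list())
  nodes <- sort(unique(c(graph$i, graph$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$i), to = as.character(graph$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  comp <- igraph::components(g)
  member <- split(nodes, comp$membership)
  subs <- lapply(member, function(v) {
    e <- graph[graph$i %in% v & graph$j %in% v, ]
    list(nodes = sort(as.integer(v)), edges = e,
         size = length(v), edge_count = nrow(e))
  })
  ord <- order(-vapply(subs, `[[`, 1L, "size"),
               -vapply(subs, `[[`, 1L, "edge_count"),
               vapply(subs, function(s) min(s$nodes), 1L))
  unname(subs[ord])
}

#' Eigenvector centrality of a connected subnetwork
#'
#' Leading eigenvector of the binary adjacency of the subnetwork's edges,
#' computed by power iteration from the uniform vector with a diagonal
#' shift (which leaves the eigenvector unchanged but suppresses the
#' oscillation a bipartite spectrum would cause). Entries are nonnegative
#' and Euclidean-normalised to 1 within the subnetwork.
#'
#' @param subnet A subnetwork from [connected_components()], or an edge
#'   tibble of one connected component.
#' @param tol Convergence tolerance on the iterate difference.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return A named numeric vector, node id -> centrality.
#' @export
eigenvector_centrality <- function(subnet, tol = 1e-10, max_iter = 10000) {
  edges <- if (is.data.frame(subnet)) subnet else subnet$edges
  nodes <- if (is.data.frame(subnet)) sort(unique(c(subnet$i, subnet$j))) else subnet$nodes
  k <- length(nodes)
  if (k < 2) stop("subnetwork needs >= 2 nodes", call. = FALSE)
  A <- matrix(0, k, k)
  ii <- match(edges$i, nodes); jj <- match(edges$j, nodes)
  A[cbind(ii, jj)] <- 1; A[cbind(jj, ii)] <- 1
  v <- rep(1 / sqrt(k), k)
  shift <- 1           # A + shift*I has the same eigenvectors, all eigenvalues positive
  for (it in seq_len(max_iter)) {
    w <- A %*% v + shift * v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) {
      out <- abs(drop(w))
      names(out) <- nodes
      return(out)
    }
    v <- w
  }
  stop("eigenvector centrality did not converge in ", max_iter, " iterations",
       call. = FALSE)
}

#' Hub nodes of a subnetwork
#'
#' A node is a hub when its eigenvector centrality is strictly greater than
#' the subnetwork mean plus one sample standard deviation (n - 1
#' denominator) of the centrality distribution. When all centralities are
#' equal the SD is zero and, by the strict inequality, there are no hubs.
#'
#' @param centralities Named numeric vector from
#'   [eigenvector_centrality()].
#' @param n_sd Number of SDs above the mean required (default 1).
#' @return Integer vector of hub node ids (possibly empty).
#' @export
find_hubs <- function(centralities, n_sd = 1) {
  if (length(centralities) < 2) stop("need >= 2 nodes", call. = FALSE)
  cutoff <- mean(centralities) + n_sd * stats::sd(centralities)
  as.integer(names(centralities)[centralities > cutoff])
}

#' Degree of a node within a subnetwork
#'
#' @param subnet A subnetwork from [connected_components()].
#' @param node Node id; must be a member.
#' @return Count of incident member edges.
#' @export
node_degree <- function(subnet, node) {
  if (!node %in% subnet$nodes) stop("node ", node, " not in subnetwork", call. = FALSE)
  sum(subnet$edges$i == node) + sum(subnet$edges$j == node)
}

#' Subnetwork report for a completed contrast
#'
#' Extracts connected components of the significant-edge graph and, per
#' subnetwork, each member's degree, eigenvector centrality and hub status,
#' joined with the atlas labels.
#'
#' @param contrast A completed `contrast_result`.
#' @param atlas The cohort's atlas (see [cohort_atlas()]); optional.
#' @return A tibble with columns `subnetwork` (1 = largest), `node_id`,
#'   `degree`, `centrality`, `is_hub` and, when an atlas is given,
#'   `hemisphere`, `network_label`, `region_label`. The component list is
#'   attached as attribute `"components"`.
#' @export
extract_subnetworks <- function(contrast, atlas = NULL) {
  comps <- connected_components(difference_graph(contrast))
  rows <- purrr::imap(comps, function(s, k) {
    cent <- if (s$size >= 2) eigenvector_centrality(s) else
      stats::setNames(1, s$nodes)
    hubs <- if (s$size >= 2) find_hubs(cent) else integer(0)
    tibble::tibble(
      subnetwork = k, node_id = s$nodes,
      degree = vapply(s$nodes, function(v) node_degree(s, v), 1L),
      centrality = unname(cent[as.character(s$nodes)]),
      is_hub = s$nodes %in% hubs)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(subnetwork = integer(0), node_id = integer(0),
                          degree = integer(0), centrality = numeric(0),
                          is_hub = logical(0))
  }
  if (!is.null(atlas)) {
    out <- dplyr::left_join(out, atlas, by = "node_id")
  }
  attr(out, "components") <- comps
  out
}
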