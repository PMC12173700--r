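#' Node set of the largest subnetwork
#'
#' Nodes of the first connected component of a contrast's difference graph
#' under the subnetwork sort order (size, then edge count, then smallest
#' member id). Empty when there are no significant edges.
#'
#' @param contrast A `contrast_result`.
#' @return Sorted integer vector of node ids.
#' @export
largest_subnetwork_nodes <- function(contrast) {
  comps <- connected_components(difference_graph(contrast))
  if (length(comps) == 0) return(integer(0))
  comps[[1]]$nodes
}

#' Intersection of two node sets
#'
#' @param a,b Integer node-id vectors over the same atlas.
#' @return Sorted integer vector of shared node ids.
#' @export
intersect_nodes <- function(a, b) sort(intersect(as.integer(a), as.integer(b)))

#' Node-identity null for the structural-functional intersect
#'
#' For each of `G` iterations, group labels are permuted within each
#' modality (group sizes preserved; independently per modality by default,
#' since the post-QC subject sets usually differ), the edge-wise scan is
#' re-run at `alpha`, each modality's largest-component node set is taken,
#' and the members of their intersection are recorded. The inner analyses
#' use the alpha-candidate graphs directly (no nested per-edge permutation).
#'
#' @param cohort A QC'd cohort carrying both modalities.
#' @param alpha Candidate threshold of the inner scans.
#' @param G Number of iterations.
#' @param seed Integer seed.
#' @param shared_relabeling Use one relabeling for both modalities per
#'   iteration; only valid when both modalities retain identical subjects.
#' @param chunk Iterations per vectorised block (memory knob).
#' @return Named integer vector over all atlas nodes: how often each node
#'   appeared in a null intersect.
#' @export
overlap_null <- function(cohort, alpha = 0.001, G = 10000, seed = 1L,
                         shared_relabeling = FALSE, chunk = 250) {
  n <- nrow(cohort_atlas(cohort))
  counts <- stats::setNames(integer(n), seq_len(n))
  if (G == 0) return(counts)
  pairs <- edge_pairs(n)
  mods <- c("dmri", "rsfmri")
  ev <- lapply(mods, function(m) edge_value_matrix(cohort, m))
  names(ev) <- mods
  if (shared_relabeling &&
      !identical(ev$dmri$subject_id, ev$rsfmri$subject_id)) {
    stop("shared_relabeling needs identical subject sets in both modalities",
         call. = FALSE)
  }
  pre <- lapply(ev, function(e) mw_precompute(e$V, e$nA))
  # critical |z| per edge for p_param < alpha given the tie-corrected sigma:
  # p = 2*pnorm(-|z|) < alpha  <=>  |z| > qnorm(1 - alpha/2)
  zcrit <- stats::qnorm(1 - alpha / 2)
  scheds <- list(
    dmri = build_schedule(pre$dmri$nA, pre$dmri$nB, G,
                          child_seed(seed, "overlap_dmri")),
    rsfmri = if (shared_relabeling) NULL else
      build_schedule(pre$rsfmri$nA, pre$rsfmri$nB, G,
                     child_seed(seed, "overlap_rsfmri")))
  done <- 0L
  while (done < G) {
    take <- seq_len(min(chunk, G - done)) + done
    cand <- lapply(mods, function(m) {
      sch <- if (shared_relabeling && m == "rsfmri") scheds$dmri else scheds[[m]]
      z <- abs(mw_z_for_assign(pre[[m]], sch$assign[, take, drop = FALSE]))
      z > zcrit                                  # nE x |take|
    })
    names(cand) <- mods
    for (k in seq_along(take)) {
      ed <- lapply(mods, function(m) which(cand[[m]][, k]))
      if (any(lengths(ed) == 0)) next
      tops <- lapply(ed, function(e) {
        comps <- connected_components(pairs[e, ])
        comps[[1]]$nodes
      })
      hit <- intersect_nodes(tops[[1]], tops[[2]])
      counts[hit] <- counts[hit] + 1L
    }
    done <- done + length(take)
  }
  counts
}

#' Per-node p-values from null appearance counts
#'
#' `p_i = count_i / G`: the fraction of null iterations in which node `i`
#' appeared in the intersect. With `add_one = TRUE` the estimator is
#' `(count_i + 1) / (G + 1)`, which cannot be exactly zero.
#'
#' @param counts Named integer vector from [overlap_null()].
#' @param G Number of iterations the counts were accumulated over.
#' @param add_one Use the add-one estimator.
#' @return Named numeric vector of p-values.
#' @export
node_identity_p <- function(counts, G, add_one = FALSE) {
  if (any(counts > G)) stop("counts cannot exceed G", call. = FALSE)
  if (add_one) (counts + 1) / (G + 1) else counts / G
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values: sort ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j` capped at 1, mapped back to input order. Controls the
#' false discovery rate across the tested family.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Structural-functional overlap test
#'
#' The cross-modality statistic: intersect the node sets of the largest
#' dMRI and rsfMRI subnetworks of two completed contrasts, then assess each
#' intersect node against the node-identity permutation null
#' ([overlap_null()]) with BH correction over the observed intersect (the
#' tested family).
#'
#' @param cohort The QC'd cohort both contrasts came from.
#' @param contrast_dmri,contrast_rsfmri Completed `contrast_result`s.
#' @inheritParams overlap_null
#' @param q_crit Significance cut on the BH-adjusted q (default 0.05).
#' @return An `overlap_result` tibble: `node_id`, `null_count`, `p`, `q`,
#'   `significant`, one row per observed intersect node, with attributes
#'   `G`, `seed`, `nodes_dmri`, `nodes_rsfmri`.
#' @export
overlap_test <- function(cohort, contrast_dmri, contrast_rsfmri,
                         alpha = 0.001, G = 10000, seed = 1L,
                         shared_relabeling = FALSE, q_crit = 0.05,
                         add_one = FALSE) {
  if (contrast_dmri$n_parcels != contrast_rsfmri$n_parcels) {
    stop("contrasts are on different atlases", call. = FALSE)
  }
  nodes_d <- largest_subnetwork_nodes(contrast_dmri)
  nodes_r <- largest_subnetwork_nodes(contrast_rsfmri)
  obs <- intersect_nodes(nodes_d, nodes_r)
  counts <- overlap_null(cohort, alpha = alpha, G = G, seed = seed,
                         shared_relabeling = shared_relabeling)
  p <- node_identity_p(counts[as.character(obs)], G, add_one = add_one)
  q <- bh_adjust(p)
  out <- tibble::tibble(node_id = obs,
                        null_count = as.integer(counts[as.character(obs)]),
                        p = unname(p), q = unname(q),
                        significant = unname(q) <= q_crit)
  attr(out, "G") <- G
  attr(out, "seed") <- seed
  attr(out, "nodes_dmri") <- nodes_d
  attr(out, "nodes_rsfmri") <- nodes_r
  class(out) <- c("overlap_result", class(out))
  out
}
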