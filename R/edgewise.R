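# ---- internal vectorized Mann-Whitney machinery ------------------------
#
# All edge-wise tests share one precomputation: midranks per edge column and
# the tie-corrected variance, which are invariant under group relabeling.
# Permutation nulls then reduce to one matrix product (rank sums for each
# relabeling), which is what makes 10,000-iteration schedules cheap.

mw_precompute <- function(V, nA) {
  ns <- nrow(V); nB <- ns - nA
  R <- apply(V, 2, rank)                      # midranks, ns x nE
  tie <- vapply(seq_len(ncol(V)), function(k) {
    r <- rle(sort(V[, k]))
    sum(r$lengths^3 - r$lengths)
  }, 1.0)
  sigma2 <- nA * nB / 12 * ((ns + 1) - tie / (ns * (ns - 1)))
  list(R = R, nA = nA, nB = nB, ns = ns, mu = nA * nB / 2,
       sigma = sqrt(pmax(sigma2, 0)))
}

# z with continuity correction from a vector/matrix of group-A rank sums
mw_z_from_ranksum <- function(pre, ranksum_a) {
  U <- ranksum_a - pre$nA * (pre$nA + 1) / 2
  dev <- U - pre$mu
  z <- (dev - 0.5 * sign(dev)) / pre$sigma
  z[pre$sigma == 0] <- 0
  list(U = U, z = z)
}

# z matrix (nE x G) for a logical assignment matrix (ns x G, TRUE = group A)
mw_z_for_assign <- function(pre, assign) {
  rs <- crossprod(pre$R, assign)              # nE x G rank sums
  mw_z_from_ranksum(pre, rs)$z
}

mw_observed <- function(pre) {
  rs <- colSums(pre$R[seq_len(pre$nA), , drop = FALSE])
  uz <- mw_z_from_ranksum(pre, rs)
  p <- pmin(1, 2 * stats::pnorm(-abs(uz$z)))
  p[pre$sigma == 0] <- 1
  direction <- dplyr::case_when(
    uz$U > pre$mu ~ "higher-in-A",
    uz$U < pre$mu ~ "higher-in-B",
    TRUE ~ "tied")
  list(U = uz$U, z = uz$z, p = p, direction = direction)
}

# subjects x edges value matrix for one modality, ordered group A then B
edge_value_matrix <- function(cohort, modality) {
  sub <- check_analysable(cohort, modality)
  labs <- contrast_labels(cohort)
  sub <- sub[order(match(sub$group_label, labs)), ]
  V <- do.call(rbind, lapply(sub[[modality]], upper_values))
  list(V = V, nA = sum(sub$group_label == labs[1]),
       nB = sum(sub$group_label == labs[2]),
       subject_id = sub$subject_id,
       n_parcels = nrow(cohort_atlas(cohort)))
}

#' Mann-Whitney test for one edge
#'
#' Rank-sum comparison of one edge's connectivity values between two groups,
#' with midrank ties, tie-corrected variance and continuity correction in
#' the normal approximation. `U` counts group-A wins (`U = R_A -
#' nA(nA+1)/2`), so `U` above `nA*nB/2` means higher connectivity in A.
#' When all values are tied, `z = 0` and `p = 1`.
#'
#' @param a,b Numeric vectors of edge values for groups A and B (each of
#'   length >= 2).
#' @return A one-row tibble with `U`, `z`, `p_param`, `direction`.
#' @export
#' @examples
#' mann_whitney_edge(c(1, 2, 3), c(4, 5, 6))
mann_whitney_edge <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values", call. = FALSE)
  pre <- mw_precompute(cbind(c(a, b)), length(a))
  obs <- mw_observed(pre)
  tibble::tibble(U = obs$U, z = obs$z, p_param = obs$p,
                 direction = obs$direction)
}

#' Rosenthal effect size for a rank test
#'
#' Computes `|z| / sqrt(N)` where `z` is the Mann-Whitney normal-approximation
#' z-score and `N` the total number of subjects. Conventional magnitudes:
#' 0.1 small, 0.3 medium, 0.5 large.
#'
#' @param z z-score (sign is ignored).
#' @param n_total Total subject count, >= 1.
#' @return Nonnegative effect size.
#' @export
rosenthal_r <- function(z, n_total) {
  if (any(n_total < 1)) stop("n_total must be >= 1", call. = FALSE)
  abs(z) / sqrt(n_total)
}

#' Edge-wise group contrast over a whole connectome
#'
#' Runs the Mann-Whitney comparison for every unordered node pair in the
#' chosen modality, flags candidate edges at the uncorrected threshold
#' `p_param < alpha` (default 0.001), and attaches Rosenthal effect sizes.
#' Edges that are zero in every subject of both groups are structurally
#' absent: they are marked `tested = FALSE` and can never become candidates.
#'
#' @param cohort A QC'd cohort (see [qc_cohort()]).
#' @param modality `"dmri"` or `"rsfmri"`.
#' @param alpha Uncorrected candidate threshold.
#' @return A `contrast_result`: list with a per-edge `stats` tibble
#'   (`edge`, `i`, `j`, `U`, `z`, `p_param`, `r_effect`, `direction`,
#'   `tested`, `candidate`), plus `modality`, `alpha`, `nA`, `nB`.
#' @export
edgewise_scan <- function(cohort, modality = c("dmri", "rsfmri"),
                          alpha = 0.001) {
  modality <- match.arg(modality)
  stopifnot(alpha >= 0, alpha <= 1)
  ev <- edge_value_matrix(cohort, modality)
  pre <- mw_precompute(ev$V, ev$nA)
  obs <- mw_observed(pre)
  tested <- colSums(ev$V != 0) > 0
  pairs <- edge_pairs(ev$n_parcels)
  stats_tb <- tibble::tibble(
    edge = seq_len(nrow(pairs)), i = pairs$i, j = pairs$j,
    U = obs$U, z = obs$z, p_param = obs$p,
    r_effect = rosenthal_r(obs$z, ev$nA + ev$nB),
    direction = obs$direction, tested = tested,
    candidate = tested & obs$p < alpha
  )
  structure(list(stats = stats_tb, modality = modality, alpha = alpha,
                 nA = ev$nA, nB = ev$nB, n_parcels = ev$n_parcels,
                 subject_id = ev$subject_id),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s, %d vs %d subjects, %d/%d edges tested\n",
              x$modality, x$nA, x$nB, sum(x$stats$tested), nrow(x$stats)))
  cat(sprintf("  candidates at p < %g: %d", x$alpha, sum(x$stats$candidate)))
  if ("significant" %in% names(x$stats)) {
    cat(sprintf("; significant after permutation (p <= %g): %d",
                x$p_crit, sum(x$stats$significant)))
  }
  cat("\n")
  invisible(x)
}

#' Permutation schedule with preserved group sizes
#'
#' `G` independent uniformly random group relabelings, each assigning
#' exactly `nA` subjects to group A, reproducible from `seed`. One schedule
#' is shared by all edges of a contrast.
#'
#' @param nA,nB Group sizes.
#' @param G Number of iterations (the reference analysis uses 10,000).
#' @param seed Integer seed.
#' @return A `perm_schedule`: list with `assign` (`(nA+nB) x G` logical
#'   matrix, `TRUE` = group A), `G`, `nA`, `nB`, `seed`.
#' @export
build_schedule <- function(nA, nB, G = 10000, seed = 1L) {
  stopifnot(G >= 1, nA >= 1, nB >= 1)
  ns <- nA + nB
  withr_seed(seed, {
    assign <- vapply(seq_len(G), function(g) {
      a <- logical(ns); a[sample.int(ns, nA)] <- TRUE; a
    }, logical(ns))
  })
  structure(list(assign = assign, G = as.integer(G), nA = nA, nB = nB,
                 seed = as.integer(seed)),
            class = "perm_schedule")
}

#' Per-edge permutation test of candidate edges
#'
#' For each candidate edge the null distribution is the two-sided `|z|`
#' statistic recomputed under every relabeling of the schedule; the
#' permutation p-value is the plain proportion of null values at least as
#' large as the observed one (`add_one = TRUE` switches to the
#' `(count + 1) / (G + 1)` estimator, which cannot be exactly zero).
#' Edges with `perm_p <= p_crit` are flagged significant.
#'
#' @param cohort The cohort the contrast came from.
#' @param contrast A `contrast_result` from [edgewise_scan()].
#' @param schedule A [build_schedule()] whose sizes match the contrast.
#' @param candidates Optional integer vector of edge indices to test;
#'   defaults to the contrast's candidate set. Use `all_edges = TRUE` to
#'   test every tested edge instead.
#' @param p_crit Permutation significance cut (default 0.05).
#' @param add_one Use the add-one p estimator.
#' @param all_edges Test every non-absent edge, not only candidates.
#' @return The contrast with `perm_p` and `significant` columns filled,
#'   and fields `G`, `p_crit`.
#' @export
permutation_test_edges <- function(cohort, contrast, schedule,
                                   candidates = NULL, p_crit = 0.05,
                                   add_one = FALSE, all_edges = FALSE) {
  stopifnot(inherits(contrast, "contrast_result"),
            inherits(schedule, "perm_schedule"))
  if (schedule$nA != contrast$nA || schedule$nB != contrast$nB) {
    stop("schedule group sizes do not match the contrast", call. = FALSE)
  }
  st <- contrast$stats
  if (is.null(candidates)) {
    candidates <- if (all_edges) st$edge[st$tested] else st$edge[st$candidate]
  }
  st$perm_p <- NA_real_
  if (length(candidates)) {
    ev <- edge_value_matrix(cohort, contrast$modality)
    pre <- mw_precompute(ev$V[, candidates, drop = FALSE], ev$nA)
    z_null <- abs(mw_z_for_assign(pre, schedule$assign))   # ncand x G
    z_obs <- abs(st$z[candidates])
    count <- rowSums(z_null >= matrix(z_obs, nrow = length(z_obs),
                                      ncol = schedule$G))
    st$perm_p[candidates] <- if (add_one) {
      (count + 1) / (schedule$G + 1)
    } else {
      count / schedule$G
    }
  }
  st$significant <- !is.na(st$perm_p) & st$candidate & st$perm_p <= p_crit
  contrast$stats <- st
  contrast$G <- schedule$G
  contrast$p_crit <- p_crit
  contrast$perm_seed <- schedule$seed
  contrast
}

#' Full edge-wise contrast: scan plus permutation stage
#'
#' Convenience wrapper running [edgewise_scan()] and
#' [permutation_test_edges()] with a fresh schedule.
#'
#' @inheritParams edgewise_scan
#' @inheritParams permutation_test_edges
#' @param G Permutation iterations.
#' @param seed Integer seed for the schedule.
#' @return A completed `contrast_result`.
#' @export
run_contrast <- function(cohort, modality, alpha = 0.001, G = 10000,
                         seed = 1L, p_crit = 0.05, add_one = FALSE,
                         all_edges = FALSE) {
  contrast <- edgewise_scan(cohort, modality, alpha)
  sched <- build_schedule(contrast$nA, contrast$nB, G,
                          child_seed(seed, paste0("perm_", modality)))
  permutation_test_edges(cohort, contrast, sched, p_crit = p_crit,
                         add_one = add_one, all_edges = all_edges)
}
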