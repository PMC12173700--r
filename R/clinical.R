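#' Candidate edges for clinical correlation
#'
#' Edges whose connectivity is correlated with clinical scores: by default
#' the significant edges of the contrast having at least one endpoint among
#' the intersect nodes; `scope = "all-incident"` broadens the family to
#' every tested edge incident to an intersect node.
#'
#' @param intersect Integer vector of intersect node ids.
#' @param contrast A completed `contrast_result`.
#' @param scope `"significant"` (default) or `"all-incident"`.
#' @return A deduplicated edge tibble with columns `edge`, `i`, `j`.
#' @export
select_candidate_edges <- function(intersect, contrast,
                                   scope = c("significant", "all-incident")) {
  scope <- match.arg(scope)
  st <- contrast$stats
  base <- switch(scope,
    "significant" = if ("significant" %in% names(st)) st$significant else st$candidate,
    "all-incident" = st$tested)
  keep <- base & (st$i %in% intersect | st$j %in% intersect)
  dplyr::select(st[keep, ], "edge", "i", "j")
}

#' Pearson correlation with pairwise deletion
#'
#' Standard product-moment correlation between a clinical score and an
#' edge-connectivity vector; subjects missing either value are dropped
#' pairwise and `df = n_complete - 2`.
#'
#' @param x,y Paired numeric vectors.
#' @return A list with `r` and `df`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  list(r = stats::cor(x[ok], y[ok]), df = sum(ok) - 2L)
}

#' Permutation-FDR p-values for score-edge correlations
#'
#' For each of `G` iterations the score vector is permuted across subjects
#' and `|r|` is recomputed for every tested edge. With the default
#' `null = "per-edge"` each edge is compared with its own null; with
#' `null = "max"` every edge is compared with the per-iteration maximum
#' `|r|` over edges (strong familywise control).
#'
#' @param score Numeric score vector (one value per subject; `NA` allowed,
#'   dropped pairwise with each edge).
#' @param conn Subjects x edges connectivity matrix.
#' @param G Number of permutations (the reference analysis uses 1,000).
#' @param seed Integer seed.
#' @param null `"per-edge"` or `"max"`.
#' @param add_one Use the `(count + 1) / (G + 1)` estimator.
#' @return A list with `r_obs`, `df`, `p_perm` (one entry per edge column).
#' @export
correlation_permutation_fdr <- function(score, conn, G = 1000, seed = 1L,
                                        null = c("per-edge", "max"),
                                        add_one = FALSE) {
  null <- match.arg(null)
  if (NCOL(conn) == 0) stop("no edges to test", call. = FALSE)
  ok <- !is.na(score)
  if (sum(ok) < 3) stop("need >= 3 subjects with the score", call. = FALSE)
  if (stats::sd(score[ok]) == 0) stop("score has zero variance", call. = FALSE)
  s <- score[ok]
  V <- conn[ok, , drop = FALSE]
  r_obs <- drop(stats::cor(s, V))
  r_null <- withr_seed(seed, {
    vapply(seq_len(G), function(g) {
      abs(drop(stats::cor(sample(s), V)))
    }, numeric(ncol(V)))
  })
  r_null <- matrix(r_null, nrow = ncol(V))          # nE x G
  thr <- if (null == "max") {
    matrix(apply(r_null, 2, max), nrow = ncol(V), ncol = G, byrow = TRUE)
  } else r_null
  count <- rowSums(thr >= matrix(abs(r_obs), nrow = ncol(V), ncol = G))
  p <- if (add_one) (count + 1) / (G + 1) else count / G
  list(r_obs = r_obs, df = length(s) - 2L, p_perm = p)
}

#' Clinical score-connectivity correlations with permutation FDR
#'
#' Pearson correlations between clinical scores and the connectivity of
#' candidate edges ([select_candidate_edges()]), within the case group by
#' default (set `group = NULL` for all subjects). Permutation p-values per
#' edge ([correlation_permutation_fdr()]) are BH-adjusted within each
#' score's tested family. Edges with zero variance across the analysed
#' subjects are dropped with a message.
#'
#' @param cohort A QC'd cohort.
#' @param contrast The completed contrast whose modality supplies the
#'   connectivity values.
#' @param intersect Intersect node ids (e.g. `overlap_result$node_id`).
#' @param scores Character vector of score column names.
#' @param group Restrict to this group label (default: the first contrast
#'   label, the case group); `NULL` for all subjects.
#' @param G Number of permutations.
#' @param seed Integer seed.
#' @inheritParams select_candidate_edges
#' @inheritParams correlation_permutation_fdr
#' @return A tibble with columns `i`, `j`, `score`, `r`, `df`, `p_perm`,
#'   `q`, sorted by score then q.
#' @export
clinical_correlations <- function(cohort, contrast, intersect,
                                  scores = c("caarms_total", "spia_total",
                                             "gaf", "bacs_total"),
                                  group = contrast_labels(cohort)[1],
                                  G = 1000, seed = 1L,
                                  scope = c("significant", "all-incident"),
                                  null = c("per-edge", "max"),
                                  add_one = FALSE) {
  edges <- select_candidate_edges(intersect, contrast, scope)
  if (nrow(edges) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          score = character(0), r = numeric(0),
                          df = integer(0), p_perm = numeric(0),
                          q = numeric(0)))
  }
  sub <- with_modality(cohort, contrast$modality)
  if (!is.null(group)) sub <- sub[sub$group_label == group, ]
  conn <- do.call(rbind, lapply(sub[[contrast$modality]], function(m) {
    m[cbind(edges$i, edges$j)]
  }))
  keep <- apply(conn, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  if (!all(keep)) {
    message(sum(!keep), " candidate edge(s) with zero variance dropped")
    edges <- edges[keep, , drop = FALSE]
    conn <- conn[, keep, drop = FALSE]
  }
  out <- purrr::map(scores, function(sc) {
    res <- correlation_permutation_fdr(sub[[sc]], conn, G = G,
                                       seed = child_seed(seed, sc),
                                       null = null, add_one = add_one)
    tibble::tibble(i = edges$i, j = edges$j, score = sc,
                   r = res$r_obs, df = res$df, p_perm = res$p_perm,
                   q = bh_adjust(res$p_perm))
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$score, .data$q, .data$p_perm)
}
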