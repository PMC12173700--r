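#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-edge statistics of a contrast
#'
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @return The per-edge stats tibble (`i`, `j`, `U`, `z`, `p_param`,
#'   `r_effect`, `direction`, `tested`, `candidate`, and after the
#'   permutation stage `perm_p`, `significant`).
#' @export
tidy.contrast_result <- function(x, ...) x$stats

#' One-row summary of a contrast
#'
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @return A one-row tibble: modality, group sizes, edge counts at each
#'   stage, and the effect-size range over significant edges.
#' @export
glance.contrast_result <- function(x, ...) {
  st <- x$stats
  sig <- if ("significant" %in% names(st)) st$significant else rep(NA, nrow(st))
  r_sig <- st$r_effect[which(sig)]
  tibble::tibble(
    modality = x$modality, nA = x$nA, nB = x$nB,
    n_pairs = nrow(st), n_tested = sum(st$tested),
    n_candidates = sum(st$candidate),
    n_significant = if (anyNA(sig)) NA_integer_ else sum(sig),
    n_higher_a = if (anyNA(sig)) NA_integer_ else
      sum(st$direction[which(sig)] == "higher-in-A"),
    n_higher_b = if (anyNA(sig)) NA_integer_ else
      sum(st$direction[which(sig)] == "higher-in-B"),
    r_effect_min = if (length(r_sig)) min(r_sig) else NA_real_,
    r_effect_median = if (length(r_sig)) stats::median(r_sig) else NA_real_,
    r_effect_max = if (length(r_sig)) max(r_sig) else NA_real_)
}

#' @rdname tidy.contrast_result
#' @export
tidy.overlap_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "overlap_result")
  out
}

#' @rdname glance.contrast_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(n_intersect = nrow(x), n_significant = sum(x$significant),
                 G = attr(x, "G"),
                 n_largest_dmri = length(attr(x, "nodes_dmri")),
                 n_largest_rsfmri = length(attr(x, "nodes_rsfmri")))
}

#' @rdname glance.contrast_result
#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(
    dplyr::bind_rows(lapply(x$contrasts, glance))[1, c("nA", "nB")],
    tibble::tibble(
      n_significant_dmri = sum(x$contrasts$dmri$stats$significant),
      n_significant_rsfmri = sum(x$contrasts$rsfmri$stats$significant),
      n_subnetworks_dmri = length(attr(x$subnetworks$dmri, "components")),
      n_subnetworks_rsfmri = length(attr(x$subnetworks$rsfmri, "components")),
      n_overlap = nrow(x$overlap),
      n_overlap_significant = sum(x$overlap$significant),
      n_clinical_significant = sum(x$clinical$q <= 0.05)))
}
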