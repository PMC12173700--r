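#' Pooled-SD Cohen's d from printed summaries
#'
#' `d = |m1 - m2| / s_pooled` with `s_pooled^2 = ((n1-1) s1^2 +
#' (n2-1) s2^2) / (n1 + n2 - 2)`. Computable directly from a demographic
#' table's "mean (SD)" entries; reported magnitudes: 0.2 small, 0.5 medium,
#' 0.8 large.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return Nonnegative effect size.
#' @export
#' @examples
#' cohens_d_pooled(-0.56, 1.12, 123, 0.02, 1.00, 49)
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD is zero", call. = FALSE)
  abs(mean1 - mean2) / sp
}

#' Phi coefficient for a 2x2 table
#'
#' `phi = |ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d))`, equivalently
#' `sqrt(chi^2 / N)` for the Pearson statistic without continuity
#' correction. Rows are groups, columns outcome yes/no.
#'
#' @param tab A 2x2 matrix of nonnegative counts with all margins positive.
#' @return Effect size in `[0, 1]`.
#' @export
#' @examples
#' phi_2x2(matrix(c(12, 0, 111, 49), 2))  # anxiolytic use, case vs control
phi_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  abs(a * d - b * c) / sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and
#' two-sided p.
#'
#' @param a,b Numeric vectors (>= 2 each, nonzero variance in at least one).
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both variances zero with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mann-Whitney test with Rosenthal effect size
#'
#' Group comparison by [mann_whitney_edge()] with the Rosenthal effect size
#' `|z| / sqrt(N)`, `N` the total subject count.
#'
#' @param a,b Numeric vectors.
#' @return A list with `U`, `z`, `p`, `r`.
#' @export
mwu_rosenthal <- function(a, b) {
  st <- mann_whitney_edge(a, b)
  list(U = st$U, z = st$z, p = st$p_param,
       r = rosenthal_r(st$z, length(a) + length(b)))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed the observed table's
#' (the point-probability criterion).
#'
#' @param tab A 2x2 count matrix with positive row and column margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: zero margin", call. = FALSE)
  }
  stats::fisher.test(tab)$p.value
}

#' Demographic/clinical comparison table
#'
#' Builds a Table-1-style summary for a cohort: numeric variables compared
#' by Welch's t (with pooled-SD Cohen's d) or Mann-Whitney (with
#' Rosenthal's r), binary variables by chi-squared or Fisher's exact test
#' (with phi).
#'
#' @param cohort A cohort tibble.
#' @param numeric_vars Named character vector of numeric columns; names
#'   `"welch"`/`"rank"` choose the test (unnamed defaults to `"rank"`).
#' @param binary_vars Character vector of logical/0-1 columns; Fisher's
#'   test is used when any expected cell count is below 5.
#' @return A tibble with `variable`, `test`, `estimate_a`, `estimate_b`,
#'   `statistic`, `p`, `effect_size`, `effect_type`.
#' @export
cohort_summary_stats <- function(cohort, numeric_vars = character(0),
                                 binary_vars = character(0)) {
  labs <- contrast_labels(cohort)
  ga <- cohort$group_label == labs[1]
  rows <- list()
  tests <- if (is.null(names(numeric_vars))) {
    rep("rank", length(numeric_vars))
  } else ifelse(names(numeric_vars) == "", "rank", names(numeric_vars))
  for (k in seq_along(numeric_vars)) {
    v <- numeric_vars[[k]]
    a <- stats::na.omit(cohort[[v]][ga]); b <- stats::na.omit(cohort[[v]][!ga])
    rows[[length(rows) + 1]] <- if (tests[k] == "welch") {
      wt <- welch_t(a, b)
      tibble::tibble(variable = v, test = "welch-t",
                     estimate_a = mean(a), estimate_b = mean(b),
                     statistic = wt$t, p = wt$p,
                     effect_size = cohens_d_pooled(mean(a), stats::sd(a), length(a),
                                                   mean(b), stats::sd(b), length(b)),
                     effect_type = "cohens_d")
    } else {
      mw <- mwu_rosenthal(a, b)
      tibble::tibble(variable = v, test = "mann-whitney",
                     estimate_a = stats::median(a), estimate_b = stats::median(b),
                     statistic = mw$U, p = mw$p,
                     effect_size = mw$r, effect_type = "rosenthal_r")
    }
  }
  for (v in binary_vars) {
    x <- as.logical(cohort[[v]])
    tab <- rbind(c(sum(x[ga], na.rm = TRUE), sum(!x[ga], na.rm = TRUE)),
                 c(sum(x[!ga], na.rm = TRUE), sum(!x[!ga], na.rm = TRUE)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expected < 5)
    p <- if (use_fisher) fisher_exact_p(tab) else
      stats::chisq.test(tab, correct = FALSE)$p.value
    rows[[length(rows) + 1]] <- tibble::tibble(
      variable = v, test = if (use_fisher) "fisher" else "chisq",
      estimate_a = tab[1, 1] / sum(tab[1, ]),
      estimate_b = tab[2, 1] / sum(tab[2, ]),
      statistic = NA_real_, p = p,
      effect_size = phi_2x2(tab), effect_type = "phi")
  }
  dplyr::bind_rows(rows)
}
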