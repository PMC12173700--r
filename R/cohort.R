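#' Assemble a cohort table
#'
#' A cohort is a tibble with one row per subject and columns `subject_id`,
#' `group_label`, per-modality motion summaries (`motion_dmri`,
#' `motion_rsfmri`, in mm; `NA` if not measured), clinical scores
#' (`caarms_total`, `spia_total`, `gaf`, `bacs_total`; `NA` allowed) and two
#' list-columns `dmri` and `rsfmri` holding each subject's [connectome()]
#' (or `NULL` when the modality is missing). The atlas and the ordered pair
#' of group labels being contrasted travel as attributes.
#'
#' @param subjects A data frame with at least `subject_id` and `group_label`;
#'   missing motion/score/connectome columns are filled with `NA`/`NULL`.
#' @param atlas An atlas tibble (see [atlas_table()]).
#' @param contrast_labels Ordered pair of group labels `(A, B)`; group A is
#'   the case group in all reported directions.
#' @return A tibble of class `cd_cohort`.
#' @export
cohort_table <- function(subjects, atlas,
                         contrast_labels = unique(subjects$group_label)) {
  subjects <- tibble::as_tibble(subjects)
  stopifnot(all(c("subject_id", "group_label") %in% names(subjects)))
  for (col in c("motion_dmri", "motion_rsfmri",
                "caarms_total", "spia_total", "gaf", "bacs_total")) {
    if (is.null(subjects[[col]])) subjects[[col]] <- NA_real_
  }
  for (col in c("dmri", "rsfmri")) {
    if (is.null(subjects[[col]])) subjects[[col]] <- vector("list", nrow(subjects))
  }
  atlas <- validate_atlas(atlas)
  if (length(contrast_labels) != 2) {
    stop("contrast_labels must name exactly two groups", call. = FALSE)
  }
  if (!all(subjects$group_label %in% contrast_labels)) {
    stop("every subject's group_label must be one of the contrast labels",
         call. = FALSE)
  }
  bad_motion <- c(subjects$motion_dmri, subjects$motion_rsfmri)
  if (any(bad_motion < 0, na.rm = TRUE)) {
    stop("motion summaries must be nonnegative", call. = FALSE)
  }
  n <- nrow(atlas)
  for (col in c("dmri", "rsfmri")) {
    dims <- vapply(subjects[[col]], function(m) if (is.null(m)) n else nrow(m), 1L)
    if (any(dims != n)) {
      stop("all ", col, " connectomes must match the atlas dimension ", n,
           call. = FALSE)
    }
  }
  structure(subjects, atlas = atlas,
            contrast_labels = as.character(contrast_labels),
            class = c("cd_cohort", class(subjects)))
}

#' @rdname cohort_table
#' @param cohort A cohort tibble.
#' @export
cohort_atlas <- function(cohort) attr(cohort, "atlas")

#' @rdname cohort_table
#' @export
contrast_labels <- function(cohort) attr(cohort, "contrast_labels")

# subjects with a connectome for a modality, in cohort order
with_modality <- function(cohort, modality) {
  keep <- !vapply(cohort[[modality]], is.null, TRUE)
  cohort[keep, ]
}

check_analysable <- function(cohort, modality) {
  sub <- with_modality(cohort, modality)
  sizes <- table(factor(sub$group_label, levels = contrast_labels(cohort)))
  if (any(sizes < 2)) {
    stop("each group needs >= 2 subjects with a ", modality, " connectome",
         call. = FALSE)
  }
  sub
}

#' Exclude high-motion subjects
#'
#' Subjects whose motion summary exceeds the sample mean by more than
#' `n_sd` standard deviations are excluded from the given modality. The
#' default rule is one-sided (only high movers are dropped) and computed on
#' the pooled sample; both choices are configurable because the convention
#' varies between studies.
#'
#' @param cohort A cohort tibble; every subject must carry a motion summary
#'   for `modality`.
#' @param modality `"dmri"` or `"rsfmri"`.
#' @param n_sd Number of standard deviations beyond the mean that triggers
#'   exclusion (default 1).
#' @param sidedness `"upper"` (default) or `"two"` (also drop implausibly
#'   low movers).
#' @param scope `"pooled"` (default: one mean/SD across groups) or
#'   `"per_group"` (mean/SD within each contrast group).
#' @return A list with tibbles `kept` and `excluded`; together they
#'   partition the input rows.
#' @export
motion_exclude <- function(cohort, modality = c("dmri", "rsfmri"), n_sd = 1,
                           sidedness = c("upper", "two"),
                           scope = c("pooled", "per_group")) {
  modality <- match.arg(modality)
  sidedness <- match.arg(sidedness)
  scope <- match.arg(scope)
  mcol <- paste0("motion_", modality)
  m <- cohort[[mcol]]
  if (anyNA(m)) stop("missing ", mcol, " for some subjects", call. = FALSE)
  grp <- if (scope == "pooled") rep(1L, length(m)) else
    match(cohort$group_label, unique(cohort$group_label))
  out <- logical(length(m))
  for (g in unique(grp)) {
    sel <- grp == g
    mu <- mean(m[sel]); sdv <- stats::sd(m[sel])
    if (is.na(sdv) || sdv == 0) next
    hi <- m[sel] > mu + n_sd * sdv
    lo <- if (sidedness == "two") m[sel] < mu - n_sd * sdv else FALSE
    out[sel] <- hi | lo
  }
  list(kept = cohort[!out, ], excluded = cohort[out, ])
}

#' Apply the full quality-control stage to a cohort
#'
#' Per modality: drop high-motion subjects ([motion_exclude()]), then
#' threshold each connectome ([apply_dmri_threshold()],
#' [apply_rsfmri_threshold()]) and Fisher-z transform the functional
#' matrices ([fisher_z_transform()]). A subject excluded for one modality
#' keeps the other if it passes.
#'
#' @param cohort A cohort tibble with raw connectomes.
#' @param dmri_min_count Streamline-count threshold (default 10).
#' @param rsfmri_abs_r Correlation magnitude threshold (default 0.05).
#' @param motion_sd Motion exclusion rule width in SDs (default 1).
#' @param motion_sidedness,motion_scope Passed to [motion_exclude()].
#' @return The cohort with QC-transformed connectomes; excluded modalities
#'   are set to `NULL`, and the per-modality exclusion tables are attached
#'   as attribute `"qc_exclusions"`.
#' @export
qc_cohort <- function(cohort, dmri_min_count = 10, rsfmri_abs_r = 0.05,
                      motion_sd = 1, motion_sidedness = "upper",
                      motion_scope = "pooled") {
  exclusions <- list()
  for (mod in c("dmri", "rsfmri")) {
    has <- !vapply(cohort[[mod]], is.null, TRUE)
    if (!any(has)) next
    split <- motion_exclude(cohort[has, ], mod, n_sd = motion_sd,
                            sidedness = motion_sidedness, scope = motion_scope)
    excl_ids <- split$excluded$subject_id
    exclusions[[mod]] <- excl_ids
    cohort[[mod]][cohort$subject_id %in% excl_ids] <- list(NULL)
    cohort[[mod]] <- purrr::map(cohort[[mod]], function(m) {
      if (is.null(m)) return(NULL)
      if (mod == "dmri") {
        apply_dmri_threshold(m, dmri_min_count)
      } else {
        fisher_z_transform(apply_rsfmri_threshold(m, rsfmri_abs_r))
      }
    })
  }
  attr(cohort, "qc_exclusions") <- exclusions
  cohort
}

#' Read or write a cohort directory
#'
#' The on-disk layout is a directory with `manifest.csv` (columns
#' `subject_id`, `group_label`, `motion_dmri`, `motion_rsfmri`,
#' `caarms_total`, `spia_total`, `gaf`, `bacs_total`, `path_dmri`,
#' `path_rsfmri`; an empty path means the modality is missing),
#' `atlas.tsv`, and one matrix file (+ sidecar JSON header) per subject and
#' modality, paths relative to the directory.
#'
#' @param dir Directory path.
#' @return `read_cohort()` returns a cohort tibble; `write_cohort()` returns
#'   `dir` invisibly.
#' @export
read_cohort <- function(dir) {
  man <- readr::read_csv(file.path(dir, "manifest.csv"),
                         show_col_types = FALSE)
  atlas <- read_atlas(file.path(dir, "atlas.tsv"))
  n <- nrow(atlas)
  load_one <- function(rel, modality, sid) {
    if (is.na(rel) || rel == "") return(NULL)
    path <- file.path(dir, rel)
    hdr <- read_connectome_header(path)
    m <- read_matrix(path, n = n)
    connectome(m, hdr$subject_id %||% sid, modality, hdr$units)
  }
  man$dmri <- purrr::map2(man$path_dmri, man$subject_id,
                          ~ load_one(.x, "dmri", .y))
  man$rsfmri <- purrr::map2(man$path_rsfmri, man$subject_id,
                            ~ load_one(.x, "rsfmri", .y))
  man$path_dmri <- man$path_rsfmri <- NULL
  cohort_table(man, atlas)
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @param format Matrix format, `"dense-tsv"` or `"matrix-market"`.
#' @export
write_cohort <- function(cohort, dir, format = c("dense-tsv", "matrix-market")) {
  format <- match.arg(format)
  ext <- if (format == "dense-tsv") ".tsv" else ".mtx"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort_atlas(cohort), file.path(dir, "atlas.tsv"))
  man <- tibble::as_tibble(cohort[setdiff(names(cohort), c("dmri", "rsfmri"))])
  for (mod in c("dmri", "rsfmri")) {
    rels <- character(nrow(cohort))
    for (k in seq_len(nrow(cohort))) {
      m <- cohort[[mod]][[k]]
      if (is.null(m)) { rels[k] <- ""; next }
      rel <- paste0(cohort$subject_id[k], "_", mod, ext)
      write_matrix(m, file.path(dir, rel), format)
      write_connectome_header(m, file.path(dir, rel))
      rels[k] <- rel
    }
    man[[paste0("path_", mod)]] <- rels
  }
  readr::write_csv(man, file.path(dir, "manifest.csv"))
  invisible(dir)
}
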