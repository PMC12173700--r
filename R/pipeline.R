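#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()], defaulting to the reference
#' analysis parameters: streamline-count threshold 10, correlation
#' magnitude threshold 0.05, one-sided 1-SD motion exclusion, candidate
#' threshold `alpha = 0.001` with 10,000 contrast and overlap permutations,
#' and 1,000 clinical permutations. Unknown keys are rejected.
#'
#' @param qc,contrast,overlap,clinical Named lists overriding stage
#'   defaults (see the source of `pipeline_defaults()` for keys).
#' @param seed Integer master seed; each stage derives its own child seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = list(), contrast = list(), overlap = list(),
                            clinical = list(), seed = 1L) {
  defs <- pipeline_defaults()
  merge_stage <- function(stage, user) {
    unknown <- setdiff(names(user), names(defs[[stage]]))
    if (length(unknown)) {
      stop("unknown ", stage, " config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    utils::modifyList(defs[[stage]], user)
  }
  cfg <- list(qc = merge_stage("qc", qc),
              contrast = merge_stage("contrast", contrast),
              overlap = merge_stage("overlap", overlap),
              clinical = merge_stage("clinical", clinical),
              seed = as.integer(seed))
  with(cfg$qc, stopifnot(dmri_min_count > 0, rsfmri_abs_r > 0, motion_sd > 0))
  with(cfg$contrast, stopifnot(alpha > 0, alpha <= 1, permutations >= 1,
                               p_crit > 0, p_crit <= 1))
  stopifnot(cfg$overlap$permutations >= 1, cfg$clinical$permutations >= 1)
  structure(cfg, class = "pipeline_config")
}

pipeline_defaults <- function() {
  list(
    qc = list(dmri_min_count = 10, rsfmri_abs_r = 0.05, motion_sd = 1,
              motion_sidedness = "upper", motion_scope = "pooled"),
    contrast = list(alpha = 0.001, permutations = 10000, p_crit = 0.05,
                    add_one = FALSE),
    overlap = list(permutations = 10000, shared_relabeling = FALSE,
                   q_crit = 0.05),
    clinical = list(permutations = 1000,
                    scores = c("caarms_total", "spia_total", "gaf",
                               "bacs_total"),
                    edge_scope = "significant")
  )
}

#' Read or write a pipeline configuration file
#'
#' YAML or JSON (chosen by extension); missing keys take the defaults of
#' [pipeline_config()], unknown keys are rejected.
#'
#' @param path Config file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw <- raw %||% list()
  unknown <- setdiff(names(raw), c("qc", "contrast", "overlap", "clinical", "seed"))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pipeline_config(qc = raw$qc %||% list(), contrast = raw$contrast %||% list(),
                  overlap = raw$overlap %||% list(),
                  clinical = raw$clinical %||% list(),
                  seed = raw$seed %||% 1L)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Run the full differential-connectome pipeline
#'
#' Quality control, edge-wise permutation contrasts for both modalities,
#' subnetwork and hub extraction, the structural-functional overlap test,
#' and clinical correlations for the edges incident to the overlap nodes —
#' all deterministic given `config$seed`.
#'
#' @param cohort A raw cohort (see [cohort_table()], [read_cohort()] or
#'   [simulate_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage TSVs and a JSON
#'   summary report are written there.
#' @return A `pipeline_result` list: `cohort` (post QC), `contrasts`,
#'   `subnetworks`, `overlap`, `clinical`, and a `manifest` recording the
#'   config, per-stage seeds and timing.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  seeds <- list(contrast = child_seed(config$seed, "contrast"),
                overlap = child_seed(config$seed, "overlap"),
                clinical = child_seed(config$seed, "clinical"))
  qc <- qc_cohort(cohort,
                  dmri_min_count = config$qc$dmri_min_count,
                  rsfmri_abs_r = config$qc$rsfmri_abs_r,
                  motion_sd = config$qc$motion_sd,
                  motion_sidedness = config$qc$motion_sidedness,
                  motion_scope = config$qc$motion_scope)
  contrasts <- lapply(c(dmri = "dmri", rsfmri = "rsfmri"), function(mod) {
    run_contrast(qc, mod, alpha = config$contrast$alpha,
                 G = config$contrast$permutations, seed = seeds$contrast,
                 p_crit = config$contrast$p_crit,
                 add_one = config$contrast$add_one)
  })
  atlas <- cohort_atlas(cohort)
  subnets <- lapply(contrasts, extract_subnetworks, atlas = atlas)
  overlap <- overlap_test(qc, contrasts$dmri, contrasts$rsfmri,
                          alpha = config$contrast$alpha,
                          G = config$overlap$permutations,
                          seed = seeds$overlap,
                          shared_relabeling = config$overlap$shared_relabeling,
                          q_crit = config$overlap$q_crit)
  clinical <- dplyr::bind_rows(lapply(names(contrasts), function(mod) {
    cl <- clinical_correlations(qc, contrasts[[mod]], overlap$node_id,
                                scores = config$clinical$scores,
                                G = config$clinical$permutations,
                                seed = child_seed(seeds$clinical, mod),
                                scope = config$clinical$edge_scope)
    if (nrow(cl)) cl$modality <- mod
    cl
  }))
  manifest <- list(
    config = unclass(config), seeds = seeds,
    version = as.character(utils::packageVersion("connectomediff")),
    n_subjects = nrow(cohort), n_parcels = nrow(atlas),
    qc_exclusions = attr(qc, "qc_exclusions"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res <- structure(list(cohort = qc, contrasts = contrasts,
                        subnetworks = subnets, overlap = overlap,
                        clinical = clinical, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (mod in names(x$contrasts)) {
    st <- x$contrasts[[mod]]$stats
    cat(sprintf("  %s: %d significant edges, %d subnetworks\n", mod,
                sum(st$significant),
                length(unique(x$subnetworks[[mod]]$subnetwork))))
  }
  cat(sprintf("  overlap: %d intersect node(s), %d significant at q <= %g\n",
              nrow(x$overlap), sum(x$overlap$significant),
              x$manifest$config$overlap$q_crit))
  cat(sprintf("  clinical: %d correlation(s) with q <= 0.05\n",
              sum(x$clinical$q <= 0.05)))
  invisible(x)
}

#' Write the per-stage outputs of a pipeline run
#'
#' Per-modality edge statistics and subnetwork tables as TSV, the overlap
#' and clinical tables as TSV, and a machine-readable `report.json`
#' summarising subnetworks, hubs, overlap nodes and significant clinical
#' correlations.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(result$contrasts)) {
    readr::write_tsv(result$contrasts[[mod]]$stats,
                     file.path(dir, paste0("edges_", mod, ".tsv")))
    readr::write_tsv(result$subnetworks[[mod]],
                     file.path(dir, paste0("subnetworks_", mod, ".tsv")))
  }
  readr::write_tsv(tibble::as_tibble(result$overlap),
                   file.path(dir, "overlap.tsv"))
  readr::write_tsv(result$clinical, file.path(dir, "clinical.tsv"))
  report <- list(
    n_significant = lapply(result$contrasts,
                           function(ct) sum(ct$stats$significant)),
    hubs = lapply(result$subnetworks, function(s) {
      s[s$is_hub, c("subnetwork", "node_id", "degree", "centrality")]
    }),
    overlap_nodes = tibble::as_tibble(result$overlap),
    significant_clinical = result$clinical[result$clinical$q <= 0.05, ],
    manifest = result$manifest)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
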