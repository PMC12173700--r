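#' Simulation configuration for synthetic paired-modality cohorts
#'
#' Builds and validates the configuration driving [simulate_cohort()]. The
#' defaults describe a small but realistic two-group study: 30 subjects per
#' group on a 60-parcel atlas; streamline counts drawn from an overdispersed
#' negative binomial (mean 150, dispersion 2) on a connected random backbone;
#' functional connectomes as sample Pearson correlations of 150 time points
#' drawn from a 6-block community covariance (within-block correlation 0.3,
#' between 0.05). Group differences are planted on explicit edge lists:
#' multiplicative `(1 + delta)` on count means, additive `+/- delta` on the
#' latent correlations; `direction = "hyper"` means higher in group A.
#'
#' @param n_parcels Number of atlas parcels (nodes).
#' @param n_group_a,n_group_b Subjects per group (group A is the case group).
#' @param backbone_density Expected fraction of node pairs carrying a
#'   structural connection, in `(0, 1]`.
#' @param count_mean,count_dispersion Negative-binomial mean and `size` for
#'   backbone streamline counts.
#' @param timeseries_length Number of time points behind each functional
#'   correlation matrix.
#' @param n_blocks,rho_within,rho_between Community structure of the latent
#'   functional covariance.
#' @param planted_edges_dmri,planted_edges_rsfmri Tibbles with columns
#'   `i`, `j`, `direction` (`"hyper"`/`"hypo"`), or `NULL` for no effect.
#' @param overlap_nodes Nodes that the two planted sets share (must be
#'   touched by both); recorded as ground truth for overlap recovery.
#' @param effect_delta_dmri,effect_delta_rsfmri Effect sizes (>= 0);
#'   multiplicative on count means, additive on latent correlations.
#' @param clinical_beta,clinical_noise_sd Linear coupling of clinical scores
#'   to mean planted-edge connectivity, and the Gaussian noise SD.
#' @param clinical_scores Score columns to fill.
#' @param motion_outlier_fraction Fraction of subjects given high motion.
#' @param seed Integer seed; per-stage child seeds are derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_parcels = 60, n_group_a = 30, n_group_b = 30,
                       backbone_density = 0.2,
                       count_mean = 150, count_dispersion = 2,
                       timeseries_length = 150,
                       n_blocks = 6, rho_within = 0.3, rho_between = 0.05,
                       planted_edges_dmri = NULL,
                       planted_edges_rsfmri = NULL,
                       overlap_nodes = integer(0),
                       effect_delta_dmri = 0, effect_delta_rsfmri = 0,
                       clinical_beta = 0, clinical_noise_sd = 1,
                       clinical_scores = c("caarms_total", "spia_total",
                                           "gaf", "bacs_total"),
                       motion_outlier_fraction = 0.08,
                       seed = 1L) {
  cfg <- list(n_parcels = n_parcels, n_group_a = n_group_a,
              n_group_b = n_group_b, backbone_density = backbone_density,
              count_mean = count_mean, count_dispersion = count_dispersion,
              timeseries_length = timeseries_length, n_blocks = n_blocks,
              rho_within = rho_within, rho_between = rho_between,
              planted_edges_dmri = normalize_planted(planted_edges_dmri, n_parcels),
              planted_edges_rsfmri = normalize_planted(planted_edges_rsfmri, n_parcels),
              overlap_nodes = as.integer(overlap_nodes),
              effect_delta_dmri = effect_delta_dmri,
              effect_delta_rsfmri = effect_delta_rsfmri,
              clinical_beta = clinical_beta,
              clinical_noise_sd = clinical_noise_sd,
              clinical_scores = clinical_scores,
              motion_outlier_fraction = motion_outlier_fraction,
              seed = as.integer(seed))
  stopifnot(n_parcels >= 2, n_group_a >= 2, n_group_b >= 2,
            backbone_density > 0, backbone_density <= 1,
            count_mean > 0, count_dispersion > 0,
            timeseries_length >= 2,
            effect_delta_dmri >= 0, effect_delta_rsfmri >= 0,
            clinical_noise_sd >= 0,
            motion_outlier_fraction >= 0, motion_outlier_fraction < 0.5)
  touched <- function(pl) unique(c(pl$i, pl$j))
  if (length(cfg$overlap_nodes)) {
    if (!all(cfg$overlap_nodes %in% touched(cfg$planted_edges_dmri)) ||
        !all(cfg$overlap_nodes %in% touched(cfg$planted_edges_rsfmri))) {
      stop("overlap_nodes must be touched by both planted edge sets",
           call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

normalize_planted <- function(pl, n) {
  if (is.null(pl) || nrow(as.data.frame(pl)) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          direction = character(0)))
  }
  pl <- tibble::as_tibble(pl)
  if (!"direction" %in% names(pl)) pl$direction <- "hyper"
  ii <- pmin(pl$i, pl$j); jj <- pmax(pl$i, pl$j)
  if (any(ii == jj) || any(ii < 1) || any(jj > n)) {
    stop("planted edges must be valid unordered pairs within 1..n", call. = FALSE)
  }
  stopifnot(all(pl$direction %in% c("hyper", "hypo")))
  out <- tibble::tibble(i = as.integer(ii), j = as.integer(jj),
                        direction = pl$direction)
  dplyr::distinct(out, .data$i, .data$j, .keep_all = TRUE)
}

#' A canonical planted design with cross-modality overlap
#'
#' Convenience builder for recovery experiments: picks `n_overlap` shared
#' nodes plus `n_extra` modality-specific nodes per modality, and plants a
#' connected path-plus-chords subnetwork on each modality's node set so that
#' the planted edges form one connected component per modality and the two
#' node sets intersect exactly in the shared nodes.
#'
#' @param n_parcels Atlas size.
#' @param n_overlap Number of shared nodes.
#' @param n_extra Extra nodes private to each modality.
#' @param seed Integer seed.
#' @return A list with `planted_edges_dmri`, `planted_edges_rsfmri`,
#'   `overlap_nodes`.
#' @export
planted_overlap_design <- function(n_parcels, n_overlap = 4, n_extra = 3,
                                   seed = 1L) {
  stopifnot(n_parcels >= n_overlap + 2 * n_extra)
  withr_seed(seed, {
    nodes <- sample.int(n_parcels, n_overlap + 2 * n_extra)
    shared <- nodes[seq_len(n_overlap)]
    extra_d <- nodes[n_overlap + seq_len(n_extra)]
    extra_r <- nodes[n_overlap + n_extra + seq_len(n_extra)]
    path_edges <- function(v) {
      # a path through all nodes plus one chord for density
      e <- tibble::tibble(i = v[-length(v)], j = v[-1])
      if (length(v) > 3) e <- dplyr::bind_rows(e, tibble::tibble(i = v[1], j = v[3]))
      e$direction <- rep(c("hyper", "hypo"), length.out = nrow(e))
      e
    }
    list(planted_edges_dmri = path_edges(c(shared, extra_d)),
         planted_edges_rsfmri = path_edges(c(shared, extra_r)),
         overlap_nodes = shared)
  })
}

# run code under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random connected structural backbone
#'
#' Binary symmetric adjacency over `n` nodes: a uniform random spanning tree
#' guarantees connectedness, then each remaining pair is added independently
#' so that the expected edge fraction is about `density`.
#'
#' @param n Number of nodes.
#' @param density Target edge fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return An `n x n` 0/1 symmetric matrix with zero diagonal.
#' @export
make_backbone <- function(n, density, seed = 1L) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]", call. = FALSE)
  withr_seed(seed, {
    m <- matrix(0L, n, n)
    # random spanning tree: attach each node to a uniformly chosen earlier one
    ord <- sample.int(n)
    for (k in 2:n) {
      a <- ord[k]; b <- ord[sample.int(k - 1, 1)]
      m[a, b] <- m[b, a] <- 1L
    }
    ne <- n_node_pairs(n)
    # extra edges to reach the target density on top of the n-1 tree edges
    p_extra <- max(0, (density * ne - (n - 1)) / (ne - (n - 1)))
    extra <- stats::runif(ne) < p_extra
    up <- upper.tri(m)
    m[up] <- pmax(m[up], as.integer(extra))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0L
    m
  })
}

#' Simulate a paired dMRI + rsfMRI cohort with planted effects
#'
#' Generates, from one `sim_config`, a full cohort: streamline-count
#' connectomes on a shared backbone ([simulate_dmri()]), sample-correlation
#' connectomes from block-structured latent covariances
#' ([simulate_rsfmri()]), motion summaries with planted outliers
#' ([simulate_motion()]) and clinical scores linearly coupled to
#' planted-edge connectivity ([simulate_clinical()]). Group labels are
#' `"CHR-P"` (group A) and `"HC"` (group B). The returned `truth` records
#' the planted edges per modality, the overlap node set, the clinical
#' coupling and the planted motion outliers, so recovery can be scored.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a [cohort_table()]) and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_parcels
  atlas <- default_atlas(n, config$n_blocks)
  backbone <- make_backbone(n, config$backbone_density,
                            child_seed(config$seed, "backbone"))
  # planted structural edges are part of the anatomy by construction
  pl <- config$planted_edges_dmri
  for (k in seq_len(nrow(pl))) backbone[pl$i[k], pl$j[k]] <- backbone[pl$j[k], pl$i[k]] <- 1L

  dmri <- simulate_dmri(config, backbone)
  rsfmri <- simulate_rsfmri(config)

  nA <- config$n_group_a; nB <- config$n_group_b
  ids <- sprintf("sub-%03d", seq_len(nA + nB))
  subjects <- tibble::tibble(
    subject_id = ids,
    group_label = rep(c("CHR-P", "HC"), c(nA, nB)),
    dmri = dmri$connectomes, rsfmri = rsfmri$connectomes
  )
  subjects$dmri <- purrr::map2(subjects$dmri, ids, function(m, id) {
    connectome(m, id, "dmri", "streamline-count")
  })
  subjects$rsfmri <- purrr::map2(subjects$rsfmri, ids, function(m, id) {
    connectome(m, id, "rsfmri", "pearson-r")
  })
  cohort <- cohort_table(subjects, atlas, c("CHR-P", "HC"))

  cohort <- simulate_motion(cohort, config$motion_outlier_fraction,
                            child_seed(config$seed, "motion"))
  truth <- list(planted_edges_dmri = config$planted_edges_dmri,
                planted_edges_rsfmri = config$planted_edges_rsfmri,
                overlap_nodes = config$overlap_nodes,
                clinical_beta = config$clinical_beta,
                motion_outliers = attr(cohort, "motion_outliers"),
                backbone = backbone)
  cl <- simulate_clinical(cohort, truth, config)
  truth$clinical_edges <- cl$clinical_edges
  list(cohort = cl$cohort, truth = truth)
}

#' Simulate streamline-count connectomes
#'
#' For every backbone edge, counts are negative-binomial with mean
#' `count_mean` and dispersion `count_dispersion`; on planted edges the
#' group-A mean is multiplied by `(1 + delta)` for `"hyper"` edges and
#' divided by it for `"hypo"`. Off-backbone entries are structural zeros.
#'
#' @param config A [sim_config()].
#' @param backbone Binary adjacency from [make_backbone()]; every planted
#'   edge must lie on it.
#' @return A list with `connectomes` (list of matrices, group A then B) and
#'   `mu` (the per-group edge mean matrix).
#' @export
simulate_dmri <- function(config, backbone) {
  n <- config$n_parcels
  pl <- config$planted_edges_dmri
  on_bb <- mapply(function(i, j) backbone[i, j] == 1L, pl$i, pl$j)
  if (nrow(pl) && !all(on_bb)) {
    stop("planted dMRI edges must lie on the backbone", call. = FALSE)
  }
  bb_up <- upper_values(backbone) == 1L
  ne <- sum(bb_up)
  mu_base <- rep(config$count_mean, ne)
  mu_a <- mu_base
  if (nrow(pl)) {
    idx_all <- edge_index(pl$i, pl$j, n)
    pos <- match(idx_all, which(bb_up))
    fac <- ifelse(pl$direction == "hyper", 1 + config$effect_delta_dmri,
                  1 / (1 + config$effect_delta_dmri))
    mu_a[pos] <- mu_base[pos] * fac
  }
  withr_seed(child_seed(config$seed, "dmri"), {
    draw <- function(mu) {
      v <- numeric(length(bb_up))
      v[bb_up] <- stats::rnbinom(ne, size = config$count_dispersion, mu = mu)
      matrix_from_upper(v, n)
    }
    conns <- c(lapply(seq_len(config$n_group_a), function(s) draw(mu_a)),
               lapply(seq_len(config$n_group_b), function(s) draw(mu_base)))
  })
  list(connectomes = conns,
       mu = list(a = matrix_from_upper(replace(numeric(length(bb_up)), bb_up, mu_a), n),
                 b = matrix_from_upper(replace(numeric(length(bb_up)), bb_up, mu_base), n)))
}

# latent block covariance, optionally with planted additive deviations,
# projected to the nearest positive-definite correlation matrix
latent_covariance <- function(config, planted = NULL, sign_delta = 0) {
  n <- config$n_parcels
  block <- ((seq_len(n) - 1L) %% config$n_blocks) + 1L
  S <- matrix(config$rho_between, n, n)
  same <- outer(block, block, "==")
  S[same] <- config$rho_within
  diag(S) <- 1
  if (!is.null(planted) && nrow(planted) && sign_delta != 0) {
    for (k in seq_len(nrow(planted))) {
      d <- if (planted$direction[k] == "hyper") sign_delta else -sign_delta
      i <- planted$i[k]; j <- planted$j[k]
      S[i, j] <- S[j, i] <- S[i, j] + d
    }
  }
  project_pd(S)
}

# eigenvalue clipping at a small floor, then rescale to unit diagonal
project_pd <- function(S, floor = 1e-4) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < floor) {
    S <- e$vectors %*% diag(pmax(e$values, floor)) %*% t(e$vectors)
    S <- stats::cov2cor(S)
  }
  S
}

#' Simulate resting-state correlation connectomes
#'
#' Each subject's matrix is the sample Pearson correlation of
#' `timeseries_length` multivariate-normal draws from the group's latent
#' covariance: a block community structure, with `+/- delta` added on
#' planted edges for group A and the result projected to the nearest
#' positive-definite correlation matrix. Finite-length sampling noise is
#' therefore realistic by construction.
#'
#' @param config A [sim_config()].
#' @return A list with `connectomes` (list of matrices, group A then B) and
#'   `sigma` (the two latent covariance matrices).
#' @export
simulate_rsfmri <- function(config) {
  n <- config$n_parcels; T_len <- config$timeseries_length
  if (T_len < n / 2) {
    warning("timeseries_length < n_parcels/2: sample correlations unstable",
            call. = FALSE)
  }
  S_b <- latent_covariance(config)
  S_a <- latent_covariance(config, config$planted_edges_rsfmri,
                           config$effect_delta_rsfmri)
  withr_seed(child_seed(config$seed, "rsfmri"), {
    draw <- function(S) {
      x <- MASS::mvrnorm(T_len, mu = rep(0, n), Sigma = S)
      r <- stats::cor(x)
      diag(r) <- 0
      r
    }
    conns <- c(lapply(seq_len(config$n_group_a), function(s) draw(S_a)),
               lapply(seq_len(config$n_group_b), function(s) draw(S_b)))
  })
  list(connectomes = conns, sigma = list(a = S_a, b = S_b))
}

#' Simulate motion summaries with planted outliers
#'
#' Baseline per-subject motion (mean relative RMS displacement, mm) is drawn
#' from a tight gamma distribution (mean 0.2 mm, SD 0.04 mm); a random
#' `outlier_fraction` of subjects receive 10x their baseline value in both
#' modalities. The planted outlier ids are attached as attribute
#' `"motion_outliers"`.
#'
#' @param cohort A cohort tibble.
#' @param outlier_fraction Fraction of subjects made high-motion.
#' @param seed Integer seed.
#' @return The cohort with `motion_dmri` and `motion_rsfmri` filled.
#' @export
simulate_motion <- function(cohort, outlier_fraction = 0.08, seed = 1L) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 0.5)
  ns <- nrow(cohort)
  withr_seed(seed, {
    base_d <- stats::rgamma(ns, shape = 25, rate = 125)
    base_r <- stats::rgamma(ns, shape = 25, rate = 125)
    n_out <- round(outlier_fraction * ns)
    out_idx <- if (n_out > 0) sample.int(ns, n_out) else integer(0)
    base_d[out_idx] <- base_d[out_idx] * 10
    base_r[out_idx] <- base_r[out_idx] * 10
  })
  cohort$motion_dmri <- base_d
  cohort$motion_rsfmri <- base_r
  attr(cohort, "motion_outliers") <- cohort$subject_id[out_idx]
  cohort
}

#' Simulate clinical scores coupled to planted connectivity
#'
#' Each configured score is `beta * (subject mean connectivity over the
#' designated planted-edge subset) + N(0, noise_sd)`. By default every score
#' is coupled to the planted dMRI edges; which subset feeds which score is
#' returned so that correlation recovery can be checked.
#'
#' @param cohort A cohort tibble whose subjects carry connectomes.
#' @param truth Ground-truth list from [simulate_cohort()] (needs
#'   `planted_edges_dmri`).
#' @param config A [sim_config()].
#' @return A list with the updated `cohort` and `clinical_edges`, the map
#'   score -> designated edge tibble.
#' @export
simulate_clinical <- function(cohort, truth, config) {
  edges <- truth$planted_edges_dmri
  clinical_edges <- stats::setNames(
    rep(list(edges), length(config$clinical_scores)), config$clinical_scores)
  mean_conn <- vapply(cohort$dmri, function(m) {
    if (is.null(m)) return(NA_real_)
    if (nrow(edges) == 0) return(0)
    mean(m[cbind(edges$i, edges$j)])
  }, 1.0)
  withr_seed(child_seed(config$seed, "clinical"), {
    for (sc in config$clinical_scores) {
      cohort[[sc]] <- config$clinical_beta * mean_conn +
        stats::rnorm(nrow(cohort), 0, config$clinical_noise_sd)
    }
  })
  list(cohort = cohort, clinical_edges = clinical_edges)
}
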