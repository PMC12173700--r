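# Shared fixtures built in code at test time.

# tiny cohort with explicit connectome values for both modalities
tiny_cohort <- function(n_parcels = 6, nA = 4, nB = 4, seed = 42,
                        modalities = c("dmri", "rsfmri")) {
  set.seed(seed)
  ns <- nA + nB
  make_dmri <- function() {
    m <- matrix(rpois(n_parcels^2, 30), n_parcels)
    m <- symmetrize(m, "mean")
    connectome(m, "tmp", "dmri", "streamline-count")
  }
  make_rs <- function() {
    x <- matrix(rnorm(50 * n_parcels), 50)
    r <- cor(x); diag(r) <- 0
    connectome(r, "tmp", "rsfmri", "pearson-r")
  }
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(ns)),
    group_label = rep(c("CHR-P", "HC"), c(nA, nB)),
    motion_dmri = runif(ns, 0.1, 0.3),
    motion_rsfmri = runif(ns, 0.1, 0.3))
  if ("dmri" %in% modalities) {
    subjects$dmri <- replicate(ns, make_dmri(), simplify = FALSE)
  }
  if ("rsfmri" %in% modalities) {
    subjects$rsfmri <- replicate(ns, make_rs(), simplify = FALSE)
  }
  cohort_table(subjects, default_atlas_for_tests(n_parcels), c("CHR-P", "HC"))
}

default_atlas_for_tests <- function(n) {
  atlas_table(seq_len(n), rep(c("L", "R"), length.out = n),
              paste0("Net", (seq_len(n) - 1) %% 3 + 1),
              sprintf("region_%d", seq_len(n)))
}

# a small cohort whose dMRI edge (1,2) is hugely shifted in group A
shifted_cohort <- function(n_parcels = 8, nA = 8, nB = 8, shift = 1000,
                           seed = 7) {
  co <- tiny_cohort(n_parcels, nA, nB, seed = seed, modalities = "dmri")
  co$dmri <- purrr::map2(co$dmri, co$group_label == "CHR-P", function(m, isA) {
    v <- unclass(m)
    v[1, 2] <- v[2, 1] <- v[1, 2] + if (isA) shift else 0
    connectome(v, attr(m, "subject_id"), "dmri", "streamline-count")
  })
  co
}

# standard recovery simulation used by several suites
recovery_sim <- function(seed = 11, n_parcels = 60, clinical_beta = 0.05,
                         clinical_noise_sd = 0.5) {
  des <- planted_overlap_design(n_parcels, n_overlap = 4, n_extra = 3,
                                seed = 5)
  cfg <- sim_config(n_parcels = n_parcels,
                    planted_edges_dmri = des$planted_edges_dmri,
                    planted_edges_rsfmri = des$planted_edges_rsfmri,
                    overlap_nodes = des$overlap_nodes,
                    effect_delta_dmri = 9, count_dispersion = 6,
                    effect_delta_rsfmri = 0.4,
                    clinical_beta = clinical_beta,
                    clinical_noise_sd = clinical_noise_sd,
                    seed = seed)
  simulate_cohort(cfg)
}

edge_index_pkg <- function(i, j, n) connectomediff:::edge_index(i, j, n)
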