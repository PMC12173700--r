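test_that("make_backbone is connected, dense as requested, reproducible", {
  b1 <- make_backbone(30, 0.2, seed = 1)
  expect_identical(b1, make_backbone(30, 0.2, seed = 1))
  expect_false(identical(b1, make_backbone(30, 0.2, seed = 2)))
  expect_equal(b1, t(b1))
  expect_equal(diag(b1), rep(0L, 30))
  # connectivity via the BFS oracle
  idx <- which(upper.tri(b1) & b1 == 1)
  edges <- tibble::tibble(i = (idx - 1) %% 30 + 1, j = (idx - 1) %/% 30 + 1)
  comps <- oracle_components_bfs(edges)
  expect_equal(length(comps), 1)
  expect_equal(length(comps[[1]]), 30)
  # density: expected fraction of pairs present
  dens <- sum(upper_vals <- b1[upper.tri(b1)]) / n_node_pairs(30)
  expect_gt(dens, 0.12); expect_lt(dens, 0.30)
  expect_equal(sum(make_backbone(10, 1, seed = 1)[upper.tri(diag(10))]),
               n_node_pairs(10))
  expect_error(make_backbone(10, 0), "density")
})

test_that("simulated cohorts satisfy connectome invariants and determinism", {
  cfg <- sim_config(n_parcels = 20, n_group_a = 5, n_group_b = 5, seed = 3)
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_equal(sim1$cohort$dmri, sim2$cohort$dmri)
  expect_equal(sim1$cohort$rsfmri, sim2$cohort$rsfmri)
  expect_equal(sim1$cohort$motion_dmri, sim2$cohort$motion_dmri)
  for (m in c(sim1$cohort$dmri, sim1$cohort$rsfmri)) {
    v <- unclass(m)
    expect_equal(v, t(v))
    expect_equal(diag(v), rep(0, 20))
    expect_true(all(is.finite(v)))
  }
  expect_true(all(vapply(sim1$cohort$dmri, min, 1.0) >= 0))
  sim3 <- simulate_cohort(sim_config(n_parcels = 20, n_group_a = 5,
                                     n_group_b = 5, seed = 4))
  expect_false(identical(sim1$cohort$dmri, sim3$cohort$dmri))
})

test_that("streamline counts concentrate on the configured mean", {
  cfg <- sim_config(n_parcels = 10, n_group_a = 150, n_group_b = 150,
                    backbone_density = 1, count_mean = 150,
                    count_dispersion = 2, seed = 5)
  sim <- simulate_cohort(cfg)
  vals <- vapply(sim$cohort$dmri, function(m) m[1, 2], 1.0)
  # negative binomial: var = mu + mu^2/size
  se <- sqrt((150 + 150^2 / 2) / 300)
  expect_lt(abs(mean(vals) - 150), 3 * se)
})

test_that("planted count effects scale the group-A mean multiplicatively", {
  pl <- tibble::tibble(i = c(1, 2), j = c(2, 3),
                       direction = c("hyper", "hypo"))
  cfg <- sim_config(n_parcels = 8, n_group_a = 400, n_group_b = 400,
                    backbone_density = 1, planted_edges_dmri = pl,
                    effect_delta_dmri = 1, count_mean = 100,
                    count_dispersion = 8, seed = 6)
  sim <- simulate_cohort(cfg)
  isA <- sim$cohort$group_label == "CHR-P"
  m_hyper <- mean(vapply(sim$cohort$dmri[isA], function(m) m[1, 2], 1.0))
  m_hypo <- mean(vapply(sim$cohort$dmri[isA], function(m) m[2, 3], 1.0))
  m_ctrl <- mean(vapply(sim$cohort$dmri[!isA], function(m) m[1, 2], 1.0))
  expect_gt(m_hyper, 180); expect_lt(m_hyper, 220)   # 100 * (1+1)
  expect_gt(m_hypo, 40); expect_lt(m_hypo, 60)       # 100 / (1+1)
  expect_gt(m_ctrl, 90); expect_lt(m_ctrl, 110)
})

test_that("planted structural edges must lie on the backbone", {
  cfg <- sim_config(n_parcels = 10, planted_edges_dmri =
                      tibble::tibble(i = 1, j = 2, direction = "hyper"),
                    effect_delta_dmri = 1, seed = 7)
  bb <- make_backbone(10, 0.3, seed = 1)
  bb[1, 2] <- bb[2, 1] <- 0L
  expect_error(simulate_dmri(cfg, bb), "backbone")
})

test_that("sample correlations approach the latent correlation as T grows", {
  cfg <- sim_config(n_parcels = 6, n_group_a = 40, n_group_b = 2,
                    timeseries_length = 4000, n_blocks = 3,
                    rho_within = 0.3, rho_between = 0.05, seed = 8)
  sim <- simulate_cohort(cfg)
  isA <- sim$cohort$group_label == "CHR-P"
  # nodes 1 and 4 share block 1 (round-robin assignment over 3 blocks)
  rs <- vapply(sim$cohort$rsfmri[isA], function(m) m[1, 4], 1.0)
  se <- (1 - 0.3^2) / sqrt(4000)        # Fisher-style large-T standard error
  expect_lt(abs(mean(rs) - 0.3), 3 * se / sqrt(40))
  expect_true(all(abs(vapply(sim$cohort$rsfmri, max, 1.0)) <= 1))
})

test_that("short time series trigger the instability warning", {
  expect_warning(
    simulate_rsfmri(sim_config(n_parcels = 30, n_group_a = 2, n_group_b = 2,
                               timeseries_length = 10, seed = 9)),
    "unstable")
})

test_that("clinical coupling is recoverable and vanishes at beta = 0", {
  sim0 <- recovery_sim(seed = 51, clinical_beta = 0, clinical_noise_sd = 1)
  e <- sim0$truth$planted_edges_dmri[1, ]
  vals <- vapply(sim0$cohort$dmri, function(m) m[e$i, e$j], 1.0)
  expect_lt(abs(cor(vals, sim0$cohort$caarms_total)), 0.35)
  simx <- recovery_sim(seed = 52, clinical_beta = 0.05,
                       clinical_noise_sd = 0)
  mean_conn <- vapply(simx$cohort$dmri, function(m) {
    mean(m[cbind(simx$truth$planted_edges_dmri$i,
                 simx$truth$planted_edges_dmri$j)])
  }, 1.0)
  expect_equal(cor(mean_conn, simx$cohort$gaf), 1, tolerance = 1e-12)
})

test_that("planted motion outliers are caught by the exclusion rule", {
  co <- tiny_cohort(4, 15, 15)
  co <- simulate_motion(co, outlier_fraction = 0.1, seed = 10)
  planted <- attr(co, "motion_outliers")
  expect_equal(length(planted), 3)
  sp <- motion_exclude(co, "dmri")
  expect_true(all(planted %in% sp$excluded$subject_id))
  # without outliers, roughly the upper tail is removed (never more than ~25%)
  co0 <- simulate_motion(co, outlier_fraction = 0, seed = 11)
  sp0 <- motion_exclude(co0, "dmri")
  expect_lt(nrow(sp0$excluded) / nrow(co0), 0.25)
  expect_true(all(sp0$excluded$motion_dmri > mean(co0$motion_dmri)))
})

test_that("overlap nodes must be touched by both planted sets", {
  expect_error(
    sim_config(planted_edges_dmri = tibble::tibble(i = 1, j = 2),
               planted_edges_rsfmri = tibble::tibble(i = 3, j = 4),
               overlap_nodes = 1, effect_delta_dmri = 1,
               effect_delta_rsfmri = 0.2),
    "touched by both")
})
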