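test_that("mann_whitney_edge handles full separation and full ties", {
  st <- mann_whitney_edge(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$U, 0)
  expect_equal(st$direction, "higher-in-B")
  tied <- mann_whitney_edge(rep(2, 4), rep(2, 5))
  expect_equal(tied$U, 10)          # nA*nB/2
  expect_equal(tied$z, 0)
  expect_equal(tied$p_param, 1)
  expect_equal(tied$direction, "tied")
  expect_error(mann_whitney_edge(1, c(1, 2)), ">= 2")
})

test_that("swapping groups flips direction and z sign only", {
  set.seed(4)
  for (rep in 1:10) {
    a <- rnorm(5); b <- rnorm(7) + 0.5
    ab <- mann_whitney_edge(a, b); ba <- mann_whitney_edge(b, a)
    expect_equal(ab$z, -ba$z)
    expect_equal(ab$p_param, ba$p_param)
    expect_equal(ab$U + ba$U, 35)   # U_A + U_B = nA*nB
  }
})

test_that("U matches full enumeration exactly; p brackets exact within 0.05", {
  set.seed(5)
  for (nA in 2:4) for (nB in 2:4) {
    for (rep in 1:3) {
      # U matches enumeration exactly for continuous and heavily tied data
      a <- rnorm(nA); b <- rnorm(nB)
      got <- mann_whitney_edge(a, b)
      exact <- oracle_mwu_exact(a, b)
      expect_equal(got$U, exact$U)
      ap <- rpois(nA, 3); bp <- rpois(nB, 3)
      expect_equal(mann_whitney_edge(ap, bp)$U, oracle_mwu_exact(ap, bp)$U)
      # the normal approximation brackets the exact p within 0.05 once both
      # groups have >= 3 members (below that its worst-case error is larger,
      # an inherent property of the approximation at the extreme U)
      if (nA >= 3 && nB >= 3) {
        expect_lt(abs(got$p_param - exact$p), 0.05)
      }
    }
  }
  expect_equal(oracle_mwu_exact(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
})

test_that("normal approximation agrees with wilcox.test conventions", {
  set.seed(6)
  for (rep in 1:10) {
    a <- rnorm(12); b <- rnorm(15) + 0.3
    got <- mann_whitney_edge(a, b)
    wt <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
    expect_equal(got$U, unname(wt$statistic))
    expect_equal(got$p_param, wt$p.value, tolerance = 1e-10)
  }
})

test_that("rosenthal_r is |z|/sqrt(N)", {
  expect_equal(rosenthal_r(0, 50), 0)
  expect_equal(rosenthal_r(2, 100), 0.2)
  expect_equal(rosenthal_r(-2, 100), 0.2)
  expect_error(rosenthal_r(1, 0), ">= 1")
})

test_that("edgewise_scan flags planted edges and skips absent ones", {
  co <- shifted_cohort()
  ct <- edgewise_scan(co, "dmri")
  e12 <- edge_index_pkg(1, 2, 8)
  expect_true(ct$stats$candidate[e12])
  expect_equal(ct$stats$direction[e12], "higher-in-A")
  # alpha = 0 can never produce candidates
  expect_equal(sum(edgewise_scan(co, "dmri", alpha = 0)$stats$candidate), 0)
  # structurally absent edges are never tested
  co0 <- co
  co0$dmri <- purrr::map(co0$dmri, function(m) {
    v <- unclass(m); v[3, 4] <- v[4, 3] <- 0
    connectome(v, attr(m, "subject_id"), "dmri", "streamline-count")
  })
  st <- edgewise_scan(co0, "dmri")$stats
  expect_false(st$tested[edge_index_pkg(3, 4, 8)])
  expect_false(st$candidate[edge_index_pkg(3, 4, 8)])
})

test_that("edge statistics are invariant under subject relabeling", {
  co <- tiny_cohort(6, 5, 5)
  base <- edgewise_scan(co, "dmri")$stats
  set.seed(7)
  perm <- sample(nrow(co))
  co2 <- cohort_table(tibble::as_tibble(co)[perm, ], cohort_atlas(co),
                      contrast_labels(co))
  permuted <- edgewise_scan(co2, "dmri")$stats
  expect_equal(permuted$U, base$U)
  expect_equal(permuted$z, base$z)
  expect_equal(permuted$p_param, base$p_param)
})

test_that("build_schedule preserves sizes, reproduces, and is uniform", {
  s1 <- build_schedule(7, 5, G = 200, seed = 9)
  expect_true(all(colSums(s1$assign) == 7))
  expect_identical(s1$assign, build_schedule(7, 5, G = 200, seed = 9)$assign)
  expect_false(identical(s1$assign, build_schedule(7, 5, 200, seed = 10)$assign))
  # all C(4,2)=6 labelings of a 2v2 schedule appear about equally often
  s2 <- build_schedule(2, 2, G = 6000, seed = 1)
  key <- apply(s2$assign, 2, function(a) paste(which(a), collapse = "-"))
  freq <- table(key)
  expect_equal(length(freq), 6)
  expect_lt(max(abs(freq / 6000 - 1 / 6)), 0.025)
})

test_that("permutation p-values behave at the boundaries and respect p_crit", {
  co <- shifted_cohort()
  ct <- edgewise_scan(co, "dmri")
  sched <- build_schedule(ct$nA, ct$nB, G = 99, seed = 2)
  done <- permutation_test_edges(co, ct, sched)
  e12 <- edge_index_pkg(1, 2, 8)
  # a shift no relabeling can match: plain proportion can be exactly 0 ...
  expect_equal(done$stats$perm_p[e12], 0)
  expect_true(done$stats$significant[e12])
  # ... and the add-one estimator gives 1/(G+1)
  done1 <- permutation_test_edges(co, ct, sched, add_one = TRUE)
  expect_equal(done1$stats$perm_p[e12], 1 / 100)
  # non-candidates carry NA and are never significant
  expect_true(all(is.na(done$stats$perm_p[!done$stats$candidate])))
  expect_false(any(done$stats$significant[!done$stats$candidate]))
  # lowering p_crit never adds edges
  strict <- permutation_test_edges(co, ct, sched, p_crit = 0.001)
  expect_true(all(strict$stats$significant <= done$stats$significant))
  # schedule size mismatch is an error
  bad <- build_schedule(3, 3, G = 10, seed = 1)
  expect_error(permutation_test_edges(co, ct, bad), "sizes")
})

test_that("an observed statistic near its null median gets perm_p near 0.5", {
  co <- tiny_cohort(5, 10, 10, seed = 123)
  ct <- edgewise_scan(co, "dmri", alpha = 1)  # every tested edge a candidate
  sched <- build_schedule(ct$nA, ct$nB, G = 400, seed = 3)
  done <- permutation_test_edges(co, ct, sched)
  # under exchangeability the perm p's straddle 0.5 on average
  expect_gt(mean(done$stats$perm_p, na.rm = TRUE), 0.35)
  expect_lt(mean(done$stats$perm_p, na.rm = TRUE), 0.65)
})

test_that("planted-edge recall is monotone in the effect size", {
  recall <- vapply(c(0.5, 2, 9), function(delta) {
    des <- planted_overlap_design(40, n_overlap = 3, n_extra = 2, seed = 5)
    cfg <- sim_config(n_parcels = 40, n_group_a = 20, n_group_b = 20,
                      planted_edges_dmri = des$planted_edges_dmri,
                      planted_edges_rsfmri = des$planted_edges_rsfmri,
                      overlap_nodes = des$overlap_nodes,
                      effect_delta_dmri = delta, count_dispersion = 6,
                      seed = 21)
    sim <- simulate_cohort(cfg)
    st <- edgewise_scan(sim$cohort, "dmri")$stats
    idx <- edge_index_pkg(sim$truth$planted_edges_dmri$i,
                          sim$truth$planted_edges_dmri$j, 40)
    mean(st$candidate[idx])
  }, 1.0)
  expect_true(all(diff(recall) >= -0.1))
  expect_gt(recall[3], 0.9)
})
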