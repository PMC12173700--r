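test_that("n_node_pairs counts unordered pairs", {
  expect_equal(n_node_pairs(2), 1)
  expect_equal(n_node_pairs(10), nrow(t(utils::combn(10, 2))))
  expect_error(n_node_pairs(1), ">= 2")
})

test_that("matrix IO round-trips exactly in both formats", {
  set.seed(1)
  m <- matrix(rnorm(100), 10)
  for (fmt in c("dense-tsv", "matrix-market")) {
    path <- tempfile(fileext = if (fmt == "matrix-market") ".mtx" else ".tsv")
    write_matrix(m, path, fmt)
    expect_identical(read_matrix(path, fmt), m, label = fmt)
    unlink(path)
  }
  # zeros and sparse coordinate entries
  z <- tempfile(fileext = ".tsv")
  write_matrix(matrix(0, 3, 3), z)
  expect_equal(read_matrix(z), matrix(0, 3, 3))
  sp <- tempfile(fileext = ".mtx")
  sm <- matrix(0, 4, 4); sm[1, 2] <- sm[2, 1] <- 5
  write_matrix(sm, sp)
  expect_equal(read_matrix(sp), sm)
  unlink(c(z, sp))
})

test_that("read_matrix rejects malformed input", {
  p <- tempfile()
  writeLines(c("1\t2\t3", "4\t5\t6"), p)   # 2 x 3
  expect_error(read_matrix(p), "square")
  writeLines(c("1\t2", "3\t4"), p)
  expect_error(read_matrix(p, n = 5), "atlas size")
  unlink(p)
})

test_that("symmetrize averages directions and zeroes the diagonal", {
  m <- matrix(0, 3, 3); m[1, 2] <- 4; m[2, 1] <- 6; diag(m) <- 9
  s <- symmetrize(m, "mean")
  expect_equal(s[1, 2], 5); expect_equal(s[2, 1], 5)
  expect_equal(diag(s), rep(0, 3))
  set.seed(2)
  r <- matrix(rnorm(64), 8)
  s <- symmetrize(r, "mean")
  expected <- (r + t(r)) / 2; diag(expected) <- 0
  expect_equal(s, expected)
  expect_equal(symmetrize(r, "min")[3, 5], min(r[3, 5], r[5, 3]))
  expect_equal(symmetrize(r, "max")[3, 5], max(r[3, 5], r[5, 3]))
  expect_error(symmetrize(matrix(1, 2, 3)), "square")
})

test_that("dMRI threshold keeps entries at the cut, zeroes below, idempotent", {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 9; m[1, 3] <- m[3, 1] <- 10
  c0 <- connectome(m, "s", "dmri", "streamline-count")
  th <- apply_dmri_threshold(c0)
  expect_equal(th[1, 2], 0)
  expect_equal(th[1, 3], 10)
  expect_identical(unclass(apply_dmri_threshold(th)), unclass(th))
  expect_equal(unclass(apply_dmri_threshold(
    connectome(matrix(0, 3, 3), "s", "dmri", "streamline-count"))),
    matrix(0, 3, 3), ignore_attr = TRUE)
  rs <- connectome(matrix(0, 3, 3), "s", "rsfmri", "pearson-r")
  expect_error(apply_dmri_threshold(rs), "units")
})

test_that("rsfMRI threshold is strict in |r| and keeps sign", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.05     # exactly at the cut: removed
  m[1, 3] <- m[3, 1] <- -0.06    # above in magnitude: kept with sign
  m[2, 4] <- m[4, 2] <- 0.04
  c0 <- connectome(m, "s", "rsfmri", "pearson-r")
  th <- apply_rsfmri_threshold(c0)
  expect_equal(th[1, 2], 0)
  expect_equal(th[1, 3], -0.06)
  expect_equal(th[2, 4], 0)
  allsmall <- connectome(symmetrize(matrix(0.04, 5, 5), "mean"),
                         "s", "rsfmri", "pearson-r")
  expect_true(all(unclass(apply_rsfmri_threshold(allsmall)) == 0))
  expect_error(apply_rsfmri_threshold(symmetrize(matrix(2, 3, 3), "mean")),
               "> 1")
})

test_that("thresholds never increase any entry magnitude (property)", {
  set.seed(3)
  for (rep in 1:5) {
    cm <- symmetrize(matrix(rpois(49, 12), 7), "mean")
    rm_ <- symmetrize(matrix(runif(49, -0.9, 0.9), 7), "mean")
    expect_true(all(abs(apply_dmri_threshold(cm)) <= abs(cm)))
    expect_true(all(abs(apply_rsfmri_threshold(rm_)) <= abs(rm_)))
  }
})

test_that("Fisher z matches the closed form, is odd and monotone", {
  grid <- seq(-0.95, 0.95, by = 0.05)
  z <- fisher_z_transform(matrix(grid, 1))  # plain-matrix path
  expect_equal(drop(z), 0.5 * log((1 + grid) / (1 - grid)))
  expect_equal(fisher_z_transform(matrix(0.5, 1, 1))[1], 0.5 * log(3),
               tolerance = 1e-12)
  expect_equal(drop(fisher_z_transform(matrix(-grid, 1))), -drop(z))
  expect_true(all(diff(drop(z)) > 0))
  expect_equal(fisher_z_transform(matrix(0, 1, 1))[1], 0)
  expect_error(fisher_z_transform(matrix(1, 1, 1)), "undefined")
  # units tracked on connectome objects, zeros preserved
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 0.5
  cz <- fisher_z_transform(connectome(m, "s", "rsfmri", "pearson-r"))
  expect_equal(attr(cz, "units"), "fisher-z")
  expect_equal(cz[1, 3], 0)
})

test_that("motion exclusion implements the one-sided mean + 1 SD rule", {
  co <- tiny_cohort(4, 5, 5, modalities = "dmri")
  co$motion_dmri <- c(rep(0.1, 9), 1.0)
  sp <- motion_exclude(co, "dmri")
  # mean 0.19, sample SD 0.2846 -> cutoff 0.4746: only the 1.0 subject out
  expect_equal(sp$excluded$subject_id, co$subject_id[10])
  expect_equal(nrow(sp$kept) + nrow(sp$excluded), nrow(co))
  expect_setequal(c(sp$kept$subject_id, sp$excluded$subject_id),
                  co$subject_id)
  # identical motion: SD 0, nobody excluded
  co$motion_dmri <- rep(0.2, 10)
  expect_equal(nrow(motion_exclude(co, "dmri")$excluded), 0)
  # far-below subject never excluded one-sided, excluded two-sided
  co$motion_dmri <- c(rep(0.5, 9), 0.000001)
  expect_equal(nrow(motion_exclude(co, "dmri")$excluded), 0)
  expect_equal(motion_exclude(co, "dmri", sidedness = "two")$excluded$subject_id,
               co$subject_id[10])
  co$motion_dmri[1] <- NA
  expect_error(motion_exclude(co, "dmri"), "missing")
})

test_that("connectome constructor enforces the container invariants", {
  expect_error(connectome(matrix(1, 2, 3), "s", "dmri", "streamline-count"),
               "square")
  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(connectome(asym, "s", "dmri", "streamline-count"), "symmetric")
  neg <- symmetrize(matrix(-3, 2, 2), "mean"); neg[1, 2] <- neg[2, 1] <- -3
  expect_error(connectome(neg, "s", "dmri", "streamline-count"), "nonnegative")
  inf <- matrix(0, 2, 2); inf[1, 2] <- inf[2, 1] <- Inf
  expect_error(connectome(inf, "s", "dmri", "streamline-count"), "finite")
  ok <- connectome(diag(2) * 5, "s", "dmri", "streamline-count")
  expect_equal(diag(unclass(ok)), c(0, 0))  # diagonal forced to zero
})

test_that("atlas and cohort IO round-trip through a cohort directory", {
  co <- tiny_cohort(5, 3, 3)
  co$caarms_total <- rnorm(6)
  dir <- tempfile()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(back$caarms_total, co$caarms_total)
  expect_equal(unclass(back$dmri[[2]]), unclass(co$dmri[[2]]))
  expect_equal(unclass(back$rsfmri[[5]]), unclass(co$rsfmri[[5]]))
  expect_equal(attr(back$rsfmri[[1]], "units"), "pearson-r")
  expect_equal(cohort_atlas(back)$region_label,
               cohort_atlas(co)$region_label)
  unlink(dir, recursive = TRUE)
})
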