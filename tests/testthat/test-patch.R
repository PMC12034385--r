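test_that("conserved-site selection takes the smallest fraction with stable ties", {
  expect_error(select_conserved(rnorm(10), 0.10), "too small",
               class = "conpatch_input_error")
  v <- c(5, 1, 4, 0.5, 3, 2, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19)
  expect_equal(select_conserved(v, 0.10), c(2L, 4L))
  # ties at the cutoff go to the lower index
  expect_equal(select_conserved(c(1, 1, 1, 2, 3, 4, 5, 6, 7, 8,
                                  9, 10, 11, 12, 13, 14, 15, 16, 17, 18), 0.10),
               c(1L, 2L))
})

test_that("anchor points are plain centroids", {
  expect_equal(anchor_point(rbind(c(1, 2, 3)), 1), c(1, 2, 3))
  expect_equal(anchor_point(rbind(c(-1, 0, 0), c(1, 0, 0)), 1:2), c(0, 0, 0))
  set.seed(41)
  xyz <- random_coords(5)
  acc <- c(0, 0, 0)
  for (i in 1:5) acc <- acc + xyz[i, ]
  expect_equal(anchor_point(xyz, 1:5), acc / 5, tolerance = 1e-12)
})

test_that("the patch t-test reproduces the closed-form pooled t", {
  # construct coordinates whose anchor distances are exactly {1,2,3} for the
  # conserved group and {7,8,9} for the rest: collinear layout, anchor at 0
  xyz <- cbind(c(-1, 2, -3, 7, -8, 9, 1, -1, 0, 0), 0, 0)
  # rates: sites 1-3 lowest (conserved), anchor set = same (window irrelevant)
  rates <- c(0.01, 0.02, 0.03, 1, 2, 3, 4, 5, 0.5, 0.6)
  # choose fraction 0.3 -> m = 3, anchor = centroid of sites 1..3?? centroid
  # of (-1,2,-3) is (-2/3,0,0), not 0 -- so test pooled_t_test directly
  oracle <- brute_pooled_t(c(1, 2, 3), c(7, 8, 9))
  ours <- conpatch:::pooled_t_test(c(1, 2, 3), c(7, 8, 9), "less")
  expect_equal(ours$t, oracle$t, tolerance = 1e-12)
  expect_equal(ours$df, 4)
  expect_equal(ours$p, oracle$p, tolerance = 1e-12)
  tt <- t.test(c(1, 2, 3), c(7, 8, 9), var.equal = TRUE,
               alternative = "less")
  expect_equal(ours$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(ours$p, tt$p.value, tolerance = 1e-12)
  # two-sided option agrees with t.test as well
  tt2 <- t.test(c(1, 2, 3), c(7, 8, 9), var.equal = TRUE)
  ours2 <- conpatch:::pooled_t_test(c(1, 2, 3), c(7, 8, 9), "two.sided")
  expect_equal(ours2$p, tt2$p.value, tolerance = 1e-12)
})

test_that("patch_test anchors on weighted rates and groups on raw rates", {
  set.seed(42)
  xyz <- random_coords(30, 20)
  raw <- rnorm(30)
  wr <- weighted_rates(raw, distance_matrix(xyz), 8)
  pt <- patch_test(xyz, wr, raw = raw, fraction = 0.2, var_equal = TRUE)
  expect_equal(pt$conserved, sort(order(raw)[1:6]))
  expect_equal(pt$anchor_set, sort(order(wr)[1:6]))
  expect_equal(pt$anchor, colMeans(xyz[pt$anchor_set, ]))
  d <- sqrt(colSums((t(xyz) - pt$anchor)^2))
  oracle <- brute_pooled_t(d[pt$conserved], d[-pt$conserved])
  expect_equal(pt$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(pt$log_p, -log(oracle$p), tolerance = 1e-12)
  expect_gte(pt$log_p, 0)

  # default Welch variant agrees with stats::t.test
  ptw <- patch_test(xyz, wr, raw = raw, fraction = 0.2)
  ttw <- t.test(d[ptw$conserved], d[-ptw$conserved], alternative = "less")
  expect_equal(ptw$t_statistic, unname(ttw$statistic), tolerance = 1e-12)
  expect_equal(ptw$df, unname(ttw$parameter), tolerance = 1e-9)
  expect_equal(ptw$log_p, -log(ttw$p.value), tolerance = 1e-9)

  # degenerate geometry: all sites coincident -> p = 1, log_p = 0, warning
  same <- matrix(1, 12, 3)
  wsame <- weighted_rates(rnorm(12), distance_matrix(same), 5)
  expect_warning(pt0 <- patch_test(same, wsame, fraction = 0.2), "degenerate")
  expect_equal(pt0$log_p, 0)

  # planted tight cluster far from a diffuse remainder is overwhelming
  set.seed(43)
  cluster <- matrix(rnorm(30, sd = 0.5), 10, 3)
  rest <- matrix(rnorm(120, mean = 30, sd = 10), 40, 3)
  xyzp <- rbind(cluster, rest)
  ratep <- c(rnorm(10, -3, 0.1), rnorm(40, 0, 0.1))
  wp <- weighted_rates(ratep, distance_matrix(xyzp), 10)
  ptp <- patch_test(xyzp, wp, raw = ratep, fraction = 0.2)
  expect_gte(ptp$log_p, 8)
})

test_that("window scans pick the maximal log_p with smallest-window ties", {
  bd <- small_benchmark()
  sr <- suppressWarnings(site_rates(bd$alignment, grid = c(0.4, 0.8), k = 8))
  xyz <- bd$structure$ca
  sc <- scan_windows(sr$scores, xyz)
  expect_equal(nrow(sc$table), 20L)
  expect_equal(sc$optimal$log_p, max(sc$table$log_p))
  expect_equal(sc$optimal_window,
               sc$table$window[which.max(sc$table$log_p)])

  # all-degenerate scan: every window gives log_p 0 -> smallest window wins
  same <- matrix(0, 20, 3)
  sc0 <- scan_windows(rnorm(20), same, distance_matrix(same))
  expect_true(all(sc0$table$log_p == 0))
  expect_equal(sc0$optimal_window, 1)
  expect_false(sc0$significant)

  # rigid-motion invariance of the full scan
  theta <- -0.4
  R <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
             c(-sin(theta), 0, cos(theta)))
  xyz2 <- xyz %*% R + matrix(c(-4, 9, 2), nrow(xyz), 3, byrow = TRUE)
  sc2 <- scan_windows(sr$scores, xyz2)
  expect_equal(sc2$table$log_p, sc$table$log_p, tolerance = 1e-9)
  expect_equal(sc2$optimal_window, sc$optimal_window)

  # relabeling invariance: permuting storage order moves nothing real
  set.seed(44)
  perm <- sample(nrow(xyz))
  sc3 <- scan_windows(sr$scores[perm], xyz[perm, ])
  expect_equal(sc3$table$log_p, sc$table$log_p, tolerance = 1e-9)
})

test_that("permutation nulls are reproducible and calibrated", {
  bd <- small_benchmark()
  sr <- suppressWarnings(site_rates(bd$alignment, grid = c(0.4, 0.8), k = 8))
  xyz <- bd$structure$ca
  d <- distance_matrix(xyz)

  p1 <- permutation_null(sr$scores, xyz, d, n_perm = 8, seed = 7)
  p2 <- permutation_null(sr$scores, xyz, d, n_perm = 8, seed = 7)
  expect_identical(p1$log_p, p2$log_p)
  expect_equal(p1$below_fraction + p1$exceedance, 1)

  # constant rates: every permutation equals the unpermuted outcome
  cst <- rep(1, nrow(xyz))
  sc_cst <- suppressWarnings(scan_windows(cst, xyz, d))
  pc <- suppressWarnings(permutation_null(cst, xyz, d, n_perm = 5, seed = 1))
  expect_equal(pc$exceedance,
               as.numeric(sc_cst$optimal$log_p >= 8))
  expect_true(all(pc$log_p == pc$log_p[1]))
})

test_that("i.i.d. rates on random structures rarely reach the threshold", {
  # negative-control calibration of the full scan
  set.seed(45)
  exceed <- logical(200)
  for (i in seq_len(200)) {
    n <- sample(50:400, 1)
    st <- simulate_structure(rnorm(n), clustered_fraction = 0.3)
    xyz <- st$structure$ca
    exceed[i] <- scan_windows(rnorm(n), xyz)$significant
  }
  expect_lte(mean(exceed), 0.05)
})

test_that("fraction sweeps run independently and survive per-entry errors", {
  bd <- small_benchmark()
  sr <- suppressWarnings(site_rates(bd$alignment, grid = c(0.4, 0.8), k = 8))
  xyz <- bd$structure$ca
  d <- distance_matrix(xyz)
  fs <- fraction_sweep(sr$scores, xyz, d)
  expect_equal(fs$table$fraction, seq(0.05, 0.25, 0.05))
  single <- fraction_sweep(sr$scores, xyz, d, fractions = 0.10)
  ref <- scan_windows(sr$scores, xyz, d, fraction = 0.10)
  expect_equal(single$table$log_p, ref$optimal$log_p, tolerance = 1e-12)

  # a fraction yielding fewer than 2 sites is reported, not fatal
  fs2 <- fraction_sweep(sr$scores[1:12], xyz[1:12, ],
                        fractions = c(0.05, 0.25))
  expect_match(fs2$table$error[1], "too small")
  expect_false(is.na(fs2$table$log_p[2]))
})
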