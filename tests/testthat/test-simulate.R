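test_that("random trees are reproducible with exponential branch lengths", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$Nnode, 1L)

  ta <- simulate_tree(50, seed = 5)
  tb <- simulate_tree(50, seed = 5)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))

  # Monte-Carlo mean branch length vs the exponential's closed form
  set.seed(6)
  bl <- unlist(lapply(1:40, function(i)
    simulate_tree(20, mean_brlen = 0.1)$edge.length))
  expect_equal(mean(bl), 0.1, tolerance = 0.05)
})

test_that("alignment simulation follows the rate-scaled substitution process", {
  tree <- simulate_tree(12, seed = 7)

  # zero-rate columns are perfectly conserved
  sim <- simulate_alignment(tree, 30, 0.7, seed = 8)
  freeze <- which(sim$true_rates < 1e-4)
  rows <- do.call(rbind, strsplit(sim$alignment$seqs, ""))
  for (j in freeze) expect_length(unique(rows[, j]), 1L)

  # long branches converge to the stationary frequencies (chi-square)
  long <- tree; long$edge.length <- long$edge.length * 0 + 50
  set.seed(9)
  sml <- simulate_alignment(long, 400, 100, model = "LG")
  chars <- unlist(strsplit(sml$alignment$seqs, ""))
  sm <- conpatch:::substitution_model("LG")
  obs <- table(factor(chars, levels = conpatch:::.AA_ORDER))
  cs <- chisq.test(as.numeric(obs), p = sm$freqs)
  expect_gt(cs$p.value, 1e-4)

  # lower gamma shape means more dispersed column-wise divergence
  tree2 <- simulate_tree(40, seed = 10)
  mism_var <- function(shape, seed) {
    sim <- simulate_alignment(tree2, 200, shape, seed = seed)
    rows <- do.call(rbind, strsplit(sim$alignment$seqs, ""))
    var(apply(rows, 2, function(col) 1 - max(table(col)) / length(col)))
  }
  expect_gt(mism_var(0.5, 11), mism_var(0.9, 12))

  expect_error(simulate_alignment(tree, 10, -1, seed = 1), "gamma_shape",
               class = "conpatch_input_error")
})

test_that("synthetic chains respect spacing, self-avoidance and planting", {
  st2 <- simulate_structure(c(0.1, 0.9), clustered_fraction = 0.5, seed = 20)
  expect_equal(sqrt(sum((st2$structure$ca[1, ] - st2$structure$ca[2, ])^2)),
               3.8, tolerance = 0.8)

  set.seed(21)
  spacings <- c(); minsep <- c()
  for (i in 1:5) {
    st <- simulate_structure(rnorm(150), clustered_fraction = 0.3)
    ca <- st$structure$ca
    spacings <- c(spacings, sqrt(rowSums(diff(ca)^2)))
    d <- distance_matrix(ca)
    minsep <- c(minsep, min(d[upper.tri(d)]))
  }
  expect_equal(mean(spacings), 3.8, tolerance = 0.1)
  expect_true(all(minsep >= 3.0))

  # the planted subset is tighter than random subsets of the same size
  set.seed(22)
  st <- simulate_structure(rnorm(200), clustered_fraction = 0.3)
  ca <- st$structure$ca
  planted_spread <- mean(dist(ca[st$planted, ]))
  rand_spread <- replicate(25, mean(dist(ca[sample(200, 60), ])))
  expect_true(all(planted_spread < rand_spread))

  # the lowest-rate columns are assigned to the planted positions
  r <- rnorm(200)
  st3 <- simulate_structure(r, clustered_fraction = 0.25, seed = 23)
  low <- order(r)[1:50]
  expect_setequal(st3$column_at_position[st3$planted], low)
})

test_that("benchmark datasets wire alignment, structure and truth together", {
  bd <- simulate_benchmark(n_seq = 10, n_sites = 60, gamma_shape = 0.6,
                           seed = 30)
  expect_equal(n_columns(bd$alignment), nrow(bd$structure$residues))
  expect_equal(structure_sequence(bd$structure), bd$alignment$seqs[1])
  expect_equal(length(bd$planted), round(0.3 * 60))
  # planted positions hold the lowest true rates
  expect_setequal(order(bd$true_rates)[seq_along(bd$planted)], bd$planted)
  # identity mapping survives the sequence-based mapper
  m <- map_alignment_to_structure(bd$alignment, bd$structure)
  expect_equal(m$pairs[, 1], m$pairs[, 2])

  # bitwise reproducibility under the seed
  bd2 <- simulate_benchmark(n_seq = 10, n_sites = 60, gamma_shape = 0.6,
                            seed = 30)
  expect_identical(bd$alignment$seqs, bd2$alignment$seqs)
  expect_identical(bd$structure$ca, bd2$structure$ca)
  expect_identical(bd$true_rates, bd2$true_rates)
})

test_that("benchmark campaigns aggregate controls and reproduce exactly", {
  camp <- run_benchmark(n_datasets = 2, n_perm = 2, seed = 77,
                        strata = list(c(50, 70), c(70, 90)),
                        shape_grid = c(0.4, 0.8), k = 8)
  expect_equal(nrow(camp$table), 2L)
  expect_true(all(camp$table$perm_below >= 0 & camp$table$perm_below <= 1))
  expect_true(all(is.finite(camp$table$log_p)))
  expect_true(all(lengths(camp$perm_log_p) == 2L))
  expect_true(camp$summary$detection_rate >= 0 &&
              camp$summary$detection_rate <= 1)

  camp2 <- run_benchmark(n_datasets = 2, n_perm = 2, seed = 77,
                         strata = list(c(50, 70), c(70, 90)),
                         shape_grid = c(0.4, 0.8), k = 8)
  expect_identical(camp$table, camp2$table)
  expect_identical(camp$perm_log_p, camp2$perm_log_p)
})
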