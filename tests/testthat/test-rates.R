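test_that("Poisson-corrected distances follow the closed form with saturation", {
  aln <- aa_alignment(c("a", "b", "c"),
                      c("AAAA", "AAAV", "VVVV"))
  d <- pairwise_distance(aln)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], -log(0.75), tolerance = 1e-12)
  expect_equal(d["a", "c"], 3)  # saturation cap at p >= 0.95
  expect_equal(d, t(d))

  # gaps excluded from the overlap
  aln2 <- aa_alignment(c("a", "b"), c("AA--", "AAVV"))
  expect_equal(pairwise_distance(aln2)["a", "b"], 0)

  # disjoint coverage is an error naming the pair
  aln3 <- aa_alignment(c("x", "y"), c("AA--", "--VV"))
  expect_error(pairwise_distance(aln3), "x.*y",
               class = "conpatch_input_error")
})

test_that("neighbor joining reproduces hand-solved and additive trees", {
  # 3 taxa: hand-solved branch lengths (0.1, 0.1, 0.3)
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.1, 0.1, 0.3),
               tolerance = 1e-12)

  # additive 4-taxon matrix: NJ recovers generating topology and path lengths
  gen <- ape::read.tree(text = "((A:0.1,B:0.2):0.05,(C:0.3,D:0.15):0.05);")
  dd <- ape::cophenetic.phylo(gen)
  tr2 <- build_nj_tree(dd[c("A", "B", "C", "D"), c("A", "B", "C", "D")])
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(dd), colnames(dd)], dd,
               tolerance = 1e-10)
  expect_true(ape::dist.topo(ape::unroot(gen), tr2) == 0)

  # negative branch lengths are clamped with slack moved to the sibling
  dneg <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  trn <- build_nj_tree(dneg)
  expect_true(all(trn$edge.length >= 0))
})

test_that("discrete gamma categories average to one and match integration", {
  for (shape in c(0.3, 0.7, 2.5)) {
    r <- gamma_category_rates(shape, 16)
    expect_length(r, 16)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
    # oracle: conditional mean of the first bin by numerical integration
    q1 <- qgamma(1 / 16, shape, rate = shape)
    m1 <- integrate(function(x) x * dgamma(x, shape, rate = shape), 0, q1,
                    rel.tol = 1e-10)$value * 16
    expect_equal(r[1], m1, tolerance = 1e-6)
  }
  expect_equal(gamma_category_rates(0.7, 1), 1)
})

test_that("pruning likelihoods match an expm-based oracle and phangorn", {
  skip_if_not_installed("phangorn")
  tree <- ape::read.tree(text = "((t1:0.12,t2:0.2):0.08,(t3:0.3,t4:0.05):0.11);")
  aln <- aa_alignment(paste0("t", 1:4), c("MKV-A", "MKVCA", "MRVCA", "MKICG"))
  sm <- conpatch:::substitution_model("JTT")
  tipmat <- conpatch:::tips_for_tree(aln, tree)
  for (rate in c(0.5, 1, 2.3)) {
    ours <- conpatch:::site_category_loglik(tipmat, tree, sm, rate)
    for (col in 1:5) {
      states <- setNames(tipmat[col, ], tree$tip.label)
      expect_equal(ours[col, 1],
                   log(brute_site_lik(tree, states, sm$Q, sm$freqs, rate)),
                   tolerance = 1e-9)
    }
  }
  # whole-alignment log-likelihood against phangorn under discrete gamma
  aln2 <- simulate_alignment(tree, 60, 0.8, seed = 5, model = "JTT")$alignment
  gm <- fit_gamma_shape(aln2, tree, grid = 0.8, k = 4, model = "JTT",
                        frequencies = "model")
  dat <- phangorn::phyDat(do.call(rbind, strsplit(aln2$seqs, "")), type = "AA")
  names(dat) <- aln2$ids
  ph <- phangorn::pml(tree, dat, model = "JTT", k = 4, shape = 0.8)
  expect_equal(gm$loglik, ph$logLik, tolerance = 1e-6)
})

test_that("gamma shape fitting behaves on the grid and recovers simulated shapes", {
  tree <- simulate_tree(30, seed = 8)
  sim <- simulate_alignment(tree, 150, 0.6, seed = 9, model = "JTT")
  # single grid point is returned as-is
  gm1 <- fit_gamma_shape(sim$alignment, tree, grid = 0.42)
  expect_equal(gm1$shape, 0.42)
  # identical columns across sequences maximize at the smallest grid shape
  cst <- aa_alignment(tree$tip.label,
                      rep(strrep("MKVLWA", 5), length(tree$tip.label)))
  gmc <- fit_gamma_shape(cst, tree, grid = c(0.05, 0.5, 2))
  expect_equal(gmc$shape, 0.05)
  # simulation recovery within a broad band
  gm <- fit_gamma_shape(sim$alignment, tree,
                        grid = exp(seq(log(0.05), log(5), length.out = 20)))
  expect_gt(gm$shape, 0.3)
  expect_lt(gm$shape, 1.2)
})

test_that("empirical-Bayes scores rank conserved columns lower", {
  tree <- ape::read.tree(text = "((t1:0.3,t2:0.3):0.1,(t3:0.3,t4:0.3):0.1);")
  aln <- aa_alignment(paste0("t", 1:4), c("MAMKM", "MCMKM", "MDMRM", "MEMKM"))
  gm <- fit_gamma_shape(aln, tree, grid = c(0.5, 1), k = 8)
  sr <- site_rates_empirical_bayes(aln, tree, gm)
  # column 2 (all different) must be faster than column 4 (one change),
  # which is faster than fully conserved columns 1/3/5
  expect_gt(sr$raw[2], sr$raw[4])
  expect_gt(sr$raw[4], sr$raw[1])
  expect_equal(sr$raw[1], sr$raw[3], tolerance = 1e-12)
  expect_equal(mean(sr$scores), 0, tolerance = 1e-12)
  expect_equal(sd(sr$scores), 1, tolerance = 1e-12)

  # identical sequences: degenerate sd -> all-zero z-scores
  cst <- aa_alignment(paste0("t", 1:4), rep("MMMM", 4))
  gmc <- fit_gamma_shape(cst, tree, grid = 0.7, k = 4)
  src <- site_rates_empirical_bayes(cst, tree, gmc)
  expect_equal(src$scores, rep(0, 4))

  # all-gap column scores 0 with a warning
  gap <- aa_alignment(paste0("t", 1:4), c("M-K", "M-K", "M-R", "M-K"))
  gmg <- fit_gamma_shape(gap, tree, grid = 0.7, k = 4)
  expect_warning(srg <- site_rates_empirical_bayes(gap, tree, gmg),
                 "no information")
  expect_equal(srg$scores[2], 0)
})

test_that("scores are invariant to sequence order and independent across columns", {
  tree <- simulate_tree(10, seed = 31)
  sim <- simulate_alignment(tree, 40, 0.7, seed = 32, model = "JTT")
  aln <- sim$alignment
  gm <- fit_gamma_shape(aln, tree, grid = c(0.4, 0.7, 1.1), k = 8)
  sr <- site_rates_empirical_bayes(aln, tree, gm)

  # label invariance: permuting row storage order changes nothing
  set.seed(33)
  perm <- sample(length(aln$ids))
  aln_p <- aa_alignment(aln$ids[perm], aln$seqs[perm])
  gm_p <- fit_gamma_shape(aln_p, tree, grid = c(0.4, 0.7, 1.1), k = 8)
  sr_p <- site_rates_empirical_bayes(aln_p, tree, gm_p)
  expect_equal(sr_p$scores, sr$scores, tolerance = 1e-10)

  # column independence: shuffling the OTHER columns leaves column j's raw
  # posterior mean unchanged at a fixed shape
  j <- 7L
  rows <- do.call(rbind, strsplit(aln$seqs, ""))
  others <- setdiff(seq_len(ncol(rows)), j)
  set.seed(34)
  rows2 <- rows; rows2[, others] <- rows[, sample(others)]
  aln2 <- aa_alignment(aln$ids, apply(rows2, 1, paste, collapse = ""))
  gm_fix <- fit_gamma_shape(aln, tree, grid = gm$shape, k = 8,
                            frequencies = "model")
  gm_fix2 <- fit_gamma_shape(aln2, tree, grid = gm$shape, k = 8,
                             frequencies = "model")
  sr1 <- site_rates_empirical_bayes(aln, tree, gm_fix)
  sr2 <- site_rates_empirical_bayes(aln2, tree, gm_fix2)
  expect_equal(sr2$raw[j], sr1$raw[j], tolerance = 1e-10)
})

test_that("imported and internal rates are interchangeable downstream", {
  bd <- small_benchmark()
  sr <- suppressWarnings(site_rates(bd$alignment, grid = c(0.4, 0.8), k = 8))
  f <- tempfile()
  writeLines(sprintf("%d %s %.10f", seq_along(sr$scores),
                     strsplit(bd$alignment$seqs[1], "")[[1]], sr$scores), f)
  imp <- read_rate4site(f)
  fit_int <- conpatch(bd$alignment, bd$structure, rates = sr, coords = "ca")
  fit_imp <- conpatch(bd$alignment, bd$structure, rates = imp, coords = "ca")
  expect_equal(fit_imp$scan$table$log_p, fit_int$scan$table$log_p,
               tolerance = 1e-6)
  expect_equal(fit_imp$scan$optimal_window, fit_int$scan$optimal_window)
})
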