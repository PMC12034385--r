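# Simulation benchmark: random trees, alignments evolved with gamma rate
# heterogeneity under an empirical replacement model, and synthetic 3D
# chains in which the most conserved sites are planted as a spatial cluster.

#' Simulate a random phylogeny
#'
#' Random binary topology (sequential random splitting) with branch lengths
#' drawn from an exponential distribution.
#'
#' @param n_leaves number of tips (>= 2).
#' @param seed RNG seed (optional; when `NULL` the current RNG stream is
#'   used).
#' @param mean_brlen mean branch length in expected substitutions per site
#'   (default 0.1).
#' @param labels tip labels (default `seq1..seqN`).
#' @return a rooted `phylo` tree.
#' @export
simulate_tree <- function(n_leaves, seed = NULL, mean_brlen = 0.1,
                          labels = paste0("seq", seq_len(n_leaves))) {
  n_leaves <- as.integer(n_leaves)
  if (n_leaves < 2L) stop_input("need at least 2 leaves")
  assert_number(mean_brlen, "mean_brlen", lower = 1e-12)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE,
                   br = function(x) stats::rexp(x, rate = 1 / mean_brlen))
  tr$tip.label <- labels
  tr
}

#' Simulate an alignment with gamma rate heterogeneity
#'
#' Each column draws a rate `r ~ Gamma(shape, rate = shape)` (mean 1) and a
#' single character is evolved down the tree: stationary draw at the root,
#' then transition probabilities `exp(Q * t * r)` along each branch under
#' the chosen replacement model.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param n_sites number of alignment columns.
#' @param gamma_shape gamma shape parameter (> 0).
#' @param seed RNG seed (optional).
#' @param model `"LG"` (default) or `"JTT"`.
#' @return list with `alignment` (an [aa_alignment], rows ordered as the
#'   tree tips, reference = first tip) and `true_rates` (the sampled
#'   per-column rates).
#' @export
simulate_alignment <- function(tree, n_sites, gamma_shape, seed = NULL,
                               model = c("LG", "JTT")) {
  model <- match.arg(model)
  assert_number(gamma_shape, "gamma_shape", lower = 1e-8)
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop_input("n_sites must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sm <- substitution_model(model)
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  n_tip <- length(tr$tip.label)
  n_nodes <- n_tip + tr$Nnode
  root <- n_tip + 1L
  r <- stats::rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
  states <- matrix(NA_integer_, n_nodes, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = sm$freqs)
  UT <- upper.tri(diag(20L), diag = TRUE) * 1
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    Ee <- exp(outer(r * tr$edge.length[e], sm$lambda))
    Pr <- (sm$U[states[pa, ], , drop = FALSE] * Ee) %*% sm$Uinv
    Pr[Pr < 0] <- 0
    Pr <- Pr / rowSums(Pr)
    cum <- Pr %*% UT
    states[ch, ] <- 1L + as.integer(rowSums(cum < stats::runif(n_sites)))
  }
  seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                function(s) paste(.AA_ORDER[s], collapse = ""))
  list(alignment = aa_alignment(tr$tip.label, seqs, reference = 1L),
       true_rates = r)
}

#' Simulate a protein-like chain with a planted conserved cluster
#'
#' Generates a self-avoiding 3D random walk (consecutive steps
#' `~ Normal(ca_spacing_mean, ca_spacing_sd)` truncated above `min_dist`;
#' proposals closer than `min_dist` to any earlier point are rejected, with
#' a restart cap). Clustering of the conserved sites is enforced during
#' generation: a contiguous block of `m = round(clustered_fraction * n)`
#' steps, starting at a random chain position, is confined to a sphere of
#' globular packing radius `(3 m v / 4 pi)^(1/3)` (`v = 134` cubic
#' Angstroms per residue) around its entry point, so those positions form a
#' compact sub-domain while the rest of the chain walks freely. An
#' assignment of alignment columns to chain positions is then drawn that
#' sends the `m` lowest-rate columns to the clustered positions (the rest
#' at random).
#'
#' @param true_site_rates per-column rates; their length sets the chain
#'   length.
#' @param clustered_fraction fraction of sites planted as a cluster
#'   (default 0.30).
#' @param ca_spacing_mean mean consecutive spacing in Angstroms
#'   (default 3.8).
#' @param ca_spacing_sd spacing standard deviation (default 0.2).
#' @param min_dist self-avoidance exclusion radius in Angstroms
#'   (default 3.0).
#' @param confine_radius optional radius of a sphere confining the whole
#'   chain; the default `Inf` leaves the walk unconfined (polymer-like).
#' @param cluster_radius radius of the sphere confining the planted block;
#'   `NULL` (default) uses the globular packing radius for `m` residues.
#' @param seed RNG seed (optional).
#' @param sequence optional one-letter chain sequence (default poly-A).
#' @param max_tries proposal attempts per step before restarting.
#' @param max_restarts chain restarts before giving up.
#' @return list with `structure` (a [protein_structure]; the center of mass
#'   equals the Calpha position), `planted` (chain positions of the
#'   cluster) and `column_at_position` (alignment column assigned to each
#'   chain position).
#' @export
simulate_structure <- function(true_site_rates, clustered_fraction = 0.30,
                               ca_spacing_mean = 3.8, ca_spacing_sd = 0.2,
                               min_dist = 3.0, confine_radius = Inf,
                               cluster_radius = NULL,
                               seed = NULL, sequence = NULL,
                               max_tries = 200L, max_restarts = 50L) {
  n <- length(true_site_rates)
  if (n < 2L) stop_input("need at least 2 sites")
  assert_number(clustered_fraction, "clustered_fraction", 1e-12, 1)
  if (!is.null(seed)) set.seed(seed)
  m <- max(1L, min(n, round(clustered_fraction * n)))
  cluster_radius <- cluster_radius %||% (3 * m * 134 / (4 * pi))^(1 / 3)
  pts <- NULL
  for (restart in seq_len(max_restarts)) {
    k <- sample.int(n - m + 1L, 1L)   # start of the clustered block
    p <- matrix(0, n, 3L)
    center <- if (k == 1L) p[1L, ] else NULL
    done <- TRUE
    for (i in 2:n) {
      placed <- FALSE
      in_block <- i >= k && i < k + m
      for (try in seq_len(max_tries)) {
        len <- stats::rnorm(1L, ca_spacing_mean, ca_spacing_sd)
        if (len <= min_dist) next
        dir <- stats::rnorm(3L)
        cand <- p[i - 1L, ] + len * dir / sqrt(sum(dir^2))
        if (sum(cand^2) > confine_radius^2) next
        if (in_block && i > k &&
            sum((cand - center)^2) > cluster_radius^2) next
        if (i > 2L) {
          prev <- p[seq_len(i - 2L), , drop = FALSE]
          if (min((prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 +
                  (prev[, 3L] - cand[3L])^2) < min_dist^2) next
        }
        p[i, ] <- cand
        if (i == k) center <- cand
        placed <- TRUE
        break
      }
      if (!placed) { done <- FALSE; break }
    }
    if (done) { pts <- p; break }
  }
  if (is.null(pts))
    stop_compute("self-avoiding walk failed after %d restarts; use another seed",
                 max_restarts)
  planted <- seq.int(k, k + m - 1L)
  low_cols <- order(true_site_rates)[seq_len(m)]
  resample <- function(x) x[sample.int(length(x))]
  col_at_pos <- integer(n)
  col_at_pos[planted] <- resample(low_cols)
  col_at_pos[-planted] <- resample(setdiff(seq_len(n), low_cols))
  aa <- if (is.null(sequence)) rep("A", n) else strsplit(sequence, "")[[1L]]
  res <- data.frame(chain = "A", resno = seq_len(n), insert = "",
                    resid = names(.AA3TO1)[match(aa, .AA3TO1)],
                    aa = aa, stringsAsFactors = FALSE)
  st <- protein_structure(res, pts, pts, source = "synthetic")
  list(structure = st, planted = planted, column_at_position = col_at_pos)
}

# replace the residue identities of a structure (used when attaching the
# reference sequence of a simulated alignment to a synthetic chain)
set_structure_sequence <- function(struct, seq1) {
  aa <- strsplit(seq1, "")[[1L]]
  if (length(aa) != nrow(struct$residues))
    stop_input("sequence length does not match structure")
  struct$residues$aa <- aa
  struct$residues$resid <- names(.AA3TO1)[match(aa, .AA3TO1)]
  struct
}

#' Simulate one benchmark dataset with a planted conserved patch
#'
#' Draws a random tree, evolves an alignment with gamma rate heterogeneity,
#' generates a synthetic chain, and permutes the alignment columns (site
#' columns are exchangeable) so that the most conserved
#' `clustered_fraction` of columns occupy the spatially tightest chain
#' positions. The resulting structure sequence equals the alignment's
#' reference row, so the alignment-to-structure mapping is the identity.
#'
#' @param n_seq number of sequences (paper-range 20-200).
#' @param n_sites number of columns (paper-range 50-500).
#' @param gamma_shape gamma shape of among-site rate variation
#'   (paper-range 0.5-0.9).
#' @param clustered_fraction planted conserved fraction (default 0.30).
#' @param ca_spacing_mean mean chain spacing in Angstroms (default 3.8).
#' @param seed RNG seed (required for reproducibility).
#' @param model replacement model used for simulation (default `"LG"`).
#' @return An object of class `benchmark_dataset`: `alignment`,
#'   `true_rates`, `structure`, `planted`, `tree`, `mapping` and the
#'   generating `spec`.
#' @export
simulate_benchmark <- function(n_seq, n_sites, gamma_shape,
                               clustered_fraction = 0.30,
                               ca_spacing_mean = 3.8, seed = 1L,
                               model = c("LG", "JTT")) {
  model <- match.arg(model)
  set.seed(seed)
  tree <- simulate_tree(n_seq)
  sim <- simulate_alignment(tree, n_sites, gamma_shape, model = model)
  st <- simulate_structure(sim$true_rates, clustered_fraction,
                           ca_spacing_mean = ca_spacing_mean)
  ord <- st$column_at_position
  rows <- do.call(rbind, strsplit(sim$alignment$seqs, ""))
  seqs <- apply(rows[, ord, drop = FALSE], 1L, paste, collapse = "")
  aln <- aa_alignment(sim$alignment$ids, seqs, reference = 1L)
  struct <- set_structure_sequence(st$structure, aln$seqs[1L])
  structure(list(alignment = aln, true_rates = sim$true_rates[ord],
                 structure = struct, planted = st$planted, tree = tree,
                 mapping = identity_mapping(n_sites),
                 spec = list(n_seq = n_seq, n_sites = n_sites,
                             gamma_shape = gamma_shape,
                             clustered_fraction = clustered_fraction,
                             ca_spacing_mean = ca_spacing_mean,
                             seed = seed, model = model)),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("Benchmark dataset: %d seqs x %d sites, shape %.2f, %d planted cluster sites (seed %d)\n",
              x$spec$n_seq, x$spec$n_sites, x$spec$gamma_shape,
              length(x$planted), x$spec$seed))
  invisible(x)
}

#' Run a simulation campaign (positive and negative controls)
#'
#' Generates datasets across the five protein-size strata and runs both
#' controls on each. Following the study design, conservation is estimated
#' from the simulated alignment first, and the synthetic structure is then
#' built so that the most conserved (estimated) sites form a spatial
#' cluster; the positive control is the window scan on that structure, the
#' negative control a rate-permutation null. Fully reproducible under the
#' master seed.
#'
#' @param n_datasets number of datasets, spread round-robin over strata
#'   (default 100).
#' @param n_perm permutation replicates per dataset (default 20; 0 skips
#'   the negative control).
#' @param seed master seed.
#' @param strata list of site-count ranges (default the five ranges
#'   50-100 ... 400-500).
#' @param n_seq_range range of sequence counts (default 20-200).
#' @param shape_range range of gamma shapes (default 0.5-0.9).
#' @param clustered_fraction planted conserved fraction (default 0.30).
#' @param fraction conserved fraction used by the scan (default 0.10).
#' @param threshold significance threshold on `log_p` (default 8).
#' @param shape_grid gamma-shape grid used for rate estimation during the
#'   campaign (default 10 log-spaced points in `[0.05, 5]`).
#' @param k discrete gamma categories (default 16).
#' @param est_model replacement model for rate estimation (default JTT).
#' @param sim_model replacement model for sequence simulation (default LG).
#' @param do_fraction_sweep also sweep fractions 5-25% per dataset
#'   (default FALSE).
#' @param progress print one line per dataset (default FALSE).
#' @return An object of class `benchmark_campaign`: per-dataset `table`,
#'   `perm_log_p`, optional `sweeps`, aggregate `summary`, and `config`.
#' @export
run_benchmark <- function(n_datasets = 100L, n_perm = 20L, seed = 1L,
                          strata = list(c(50, 100), c(100, 200), c(200, 300),
                                        c(300, 400), c(400, 500)),
                          n_seq_range = c(20, 200), shape_range = c(0.5, 0.9),
                          clustered_fraction = 0.30, fraction = 0.10,
                          threshold = 8,
                          shape_grid = exp(seq(log(0.05), log(5),
                                               length.out = 10L)),
                          k = 16L, est_model = "JTT", sim_model = "LG",
                          do_fraction_sweep = FALSE, progress = FALSE) {
  n_datasets <- as.integer(n_datasets)
  if (n_datasets < 1L) stop_input("n_datasets must be >= 1")
  set.seed(seed)
  ds_seed <- sample.int(2147483646L, n_datasets)
  rows <- vector("list", n_datasets)
  perm_log_p <- vector("list", n_datasets)
  sweeps <- if (do_fraction_sweep) vector("list", n_datasets) else NULL
  for (i in seq_len(n_datasets)) {
    si <- ((i - 1L) %% length(strata)) + 1L
    set.seed(ds_seed[i])
    n_sites <- sample(seq(strata[[si]][1L], strata[[si]][2L]), 1L)
    n_seq <- sample(seq(n_seq_range[1L], n_seq_range[2L]), 1L)
    shape <- stats::runif(1L, shape_range[1L], shape_range[2L])
    # study order: simulate sequences, estimate conservation, then build a
    # structure in which the most conserved (estimated) sites are clustered
    tree <- simulate_tree(n_seq)
    sim <- simulate_alignment(tree, n_sites, shape, model = sim_model)
    sr <- suppressWarnings(site_rates(sim$alignment, grid = shape_grid,
                                      k = k, model = est_model))
    st <- simulate_structure(sr$scores,
                             clustered_fraction = clustered_fraction)
    ord <- st$column_at_position
    scores <- sr$scores[ord]
    true_rates <- sim$true_rates[ord]
    planted <- st$planted
    coords <- st$structure$ca
    dmat <- distance_matrix(coords)
    sc <- scan_windows(scores, coords, dmat, fraction = fraction,
                       threshold = threshold)
    pn <- if (n_perm > 0L)
      permutation_null(scores, coords, dmat, n_perm = n_perm,
                       fraction = fraction, threshold = threshold)
    if (do_fraction_sweep)
      sweeps[[i]] <- fraction_sweep(scores, coords, dmat,
                                    threshold = threshold)$table
    det <- sc$optimal$conserved
    ov <- length(intersect(det, planted))
    rows[[i]] <- data.frame(
      dataset = i, stratum = paste(strata[[si]], collapse = "-"),
      n_seq = n_seq, n_sites = n_sites, gamma_shape = shape,
      shape_est = sr$shape, optimal_window = sc$optimal_window,
      log_p = sc$optimal$log_p, detected = sc$significant,
      overlap = ov,
      overlap_p = stats::phyper(ov - 1L, length(planted),
                                n_sites - length(planted), length(det),
                                lower.tail = FALSE),
      spearman_true_est = stats::cor(true_rates, scores,
                                     method = "spearman"),
      perm_below = if (n_perm > 0L) pn$below_fraction else NA_real_,
      perm_max_log_p = if (n_perm > 0L) max(pn$log_p) else NA_real_,
      seed = ds_seed[i], stringsAsFactors = FALSE)
    perm_log_p[[i]] <- if (n_perm > 0L) pn$log_p else numeric()
    if (progress)
      message(sprintf("[benchmark] dataset %d/%d (%s sites): log P = %.2f",
                      i, n_datasets, rows[[i]]$stratum, rows[[i]]$log_p))
  }
  tab <- do.call(rbind, rows)
  summary <- list(
    n_datasets = n_datasets,
    detection_rate = mean(tab$detected),
    median_log_p = stats::median(tab$log_p),
    perm_below_rate = if (n_perm > 0L) mean(unlist(perm_log_p) < threshold)
                      else NA_real_,
    n_perm_total = n_perm * n_datasets,
    median_log_p_by_stratum = tapply(tab$log_p, tab$stratum, stats::median),
    median_overlap_p = stats::median(tab$overlap_p))
  structure(list(table = tab, perm_log_p = perm_log_p, sweeps = sweeps,
                 summary = summary,
                 config = list(n_datasets = n_datasets, n_perm = n_perm,
                               seed = seed, strata = strata,
                               n_seq_range = n_seq_range,
                               shape_range = shape_range,
                               clustered_fraction = clustered_fraction,
                               fraction = fraction, threshold = threshold,
                               shape_grid = shape_grid, k = k,
                               est_model = est_model, sim_model = sim_model)),
            class = "benchmark_campaign")
}

#' @export
print.benchmark_campaign <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Benchmark campaign: %d datasets\n", s$n_datasets))
  cat(sprintf("  positive-control detection rate: %.1f%%\n",
              100 * s$detection_rate))
  if (!is.na(s$perm_below_rate))
    cat(sprintf("  permutation replicates below threshold: %.1f%% (of %d)\n",
                100 * s$perm_below_rate, s$n_perm_total))
  cat(sprintf("  median optimal log P: %.2f\n", s$median_log_p))
  invisible(x)
}
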