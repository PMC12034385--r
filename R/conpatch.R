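#' Detect a conserved amino-acid patch in a protein structure
#'
#' The main entry point: maps the alignment onto the structure, obtains
#' site-specific substitution rates (estimated internally unless supplied),
#' computes spatially correlated rates for each window size, and scans
#' windows for the strongest anchored clustering of conserved sites.
#'
#' @param alignment an [aa_alignment] (or path to an aligned FASTA file).
#' @param structure a [protein_structure] (or path to a PDB file).
#' @param rates optional `site_rates` (e.g. from [read_rate4site()] or
#'   [site_rates()]); estimated internally when `NULL`.
#' @param tree optional user-supplied `phylo` tree for rate estimation.
#' @param coords coordinate mode: `"com"` (residue centers of mass,
#'   default) or `"ca"` (alpha carbons).
#' @param fraction conserved fraction (default 0.10).
#' @param w_min,w_max,step window scan range in Angstroms (default 1-20, 1).
#' @param threshold significance threshold on `log_p = -ln(p)` (default 8).
#' @param n_perm permutation replicates for the negative control
#'   (default 0 = none).
#' @param seed RNG seed, used (and recorded) when `n_perm > 0`.
#' @param chain chain to read when `structure` is a file path.
#' @param alternative t-test sidedness (default one-sided, conserved
#'   closer).
#' @param var_equal pooled-variance t instead of Welch (default FALSE).
#' @param mapping optional precomputed `residue_mapping`.
#' @param ... further arguments passed to [site_rates()] when rates are
#'   estimated internally.
#' @return An object of class `conpatch`: the fitted window scan plus the
#'   mapping, rates, coordinates and configuration. Supports `print()`,
#'   `summary()`, `plot()` and `coef()` (weighted rates at the optimal
#'   window, per structure residue).
#' @examples
#' bd <- simulate_benchmark(n_seq = 12, n_sites = 60, gamma_shape = 0.7,
#'                          seed = 7)
#' fit <- conpatch(bd$alignment, bd$structure, coords = "ca",
#'                 grid = c(0.3, 0.7, 1.5))
#' fit
#' @export
conpatch <- function(alignment, structure, rates = NULL, tree = NULL,
                     coords = c("com", "ca"), fraction = 0.10, w_min = 1,
                     w_max = 20, step = 1, threshold = 8, n_perm = 0L,
                     seed = NULL, chain = NULL,
                     alternative = c("less", "two.sided"), var_equal = FALSE,
                     mapping = NULL, ...) {
  coords <- match.arg(coords); alternative <- match.arg(alternative)
  if (is.character(alignment)) alignment <- read_fasta_alignment(alignment)
  if (is.character(structure))
    structure <- read_pdb_structure(structure, chain = chain)
  stopifnot(inherits(alignment, "aa_alignment"),
            inherits(structure, "protein_structure"))
  mapping <- mapping %||% map_alignment_to_structure(alignment, structure)
  if (is.null(rates)) rates <- site_rates(alignment, tree = tree, ...)
  stopifnot(inherits(rates, "site_rates"))
  if (length(rates$scores) != n_columns(alignment))
    stop_input("rates length (%d) does not match alignment columns (%d)",
               length(rates$scores), n_columns(alignment))
  pairs <- mapping$pairs
  if (nrow(pairs) < 4L) stop_input("fewer than 4 mapped residues")
  xyz <- (if (coords == "com") structure$com else structure$ca)[pairs[, 2L], ,
                                                                drop = FALSE]
  mapped_rates <- rates$scores[pairs[, 1L]]
  dmat <- distance_matrix(xyz)
  scan <- scan_windows(mapped_rates, xyz, dmat, w_min = w_min, w_max = w_max,
                       step = step, fraction = fraction,
                       threshold = threshold, alternative = alternative,
                       var_equal = var_equal)
  perm <- NULL
  if (n_perm > 0L) {
    perm <- permutation_null(mapped_rates, xyz, dmat, n_perm = n_perm,
                             seed = seed, fraction = fraction,
                             threshold = threshold, w_min = w_min,
                             w_max = w_max, step = step,
                             alternative = alternative,
                             var_equal = var_equal)
  }
  structure(list(scan = scan, permutation = perm, mapping = mapping,
                 rates = rates, alignment = alignment,
                 structure = structure, coords = coords, xyz = xyz,
                 mapped_rates = mapped_rates,
                 config = list(coords = coords, fraction = fraction,
                               w_min = w_min, w_max = w_max, step = step,
                               threshold = threshold, n_perm = n_perm,
                               seed = seed, alternative = alternative,
                               var_equal = var_equal,
                               rates_provenance = rates$provenance)),
            class = "conpatch")
}

#' @export
print.conpatch <- function(x, ...) {
  cat("Conserved-patch analysis\n")
  cat(sprintf("  %d alignment columns, %d structure residues, %d mapped (%s coordinates)\n",
              n_columns(x$alignment), nrow(x$structure$residues),
              nrow(x$mapping$pairs), toupper(x$coords)))
  cat(sprintf("  rates: %s\n", x$rates$provenance))
  print(x$scan)
  if (!is.null(x$permutation))
    cat(sprintf("  permutation null: %.1f%% of %d replicates below threshold\n",
                100 * x$permutation$below_fraction, x$permutation$n_perm))
  invisible(x)
}

#' @export
#' @method summary conpatch
summary.conpatch <- function(object, ...) {
  opt <- object$scan$optimal
  res <- object$structure$residues[object$mapping$pairs[opt$conserved, 2L], ]
  out <- list(
    optimal_window = object$scan$optimal_window,
    log_p = opt$log_p, t_statistic = opt$t_statistic,
    significant = object$scan$significant,
    threshold = object$scan$threshold,
    anchor = opt$anchor,
    n_conserved = length(opt$conserved),
    conserved_residues = paste0(res$resid, res$resno),
    table = object$scan$table,
    permutation = object$permutation)
  class(out) <- "summary.conpatch"
  out
}

#' @export
print.summary.conpatch <- function(x, ...) {
  cat(sprintf("Optimal window: %g A  (log P = %.2f, t = %.2f)\n",
              x$optimal_window, x$log_p, x$t_statistic))
  cat(sprintf("Patch %s at threshold %g\n",
              if (x$significant) "DETECTED" else "not detected", x$threshold))
  cat(sprintf("Anchor point: (%.2f, %.2f, %.2f) A\n",
              x$anchor[1L], x$anchor[2L], x$anchor[3L]))
  cat(sprintf("Conserved sites (%d): %s\n", x$n_conserved,
              paste(x$conserved_residues, collapse = " ")))
  invisible(x)
}

#' @export
#' @method plot conpatch
#' @importFrom graphics abline points
plot.conpatch <- function(x, ...) {
  tab <- x$scan$table
  plot(tab$window, tab$log_p, type = "b", pch = 16,
       xlab = "window size (Å)", ylab = expression(-log ~ italic(P)),
       main = "Conserved-patch window scan", ...)
  abline(h = x$scan$threshold, lty = 2)
  points(x$scan$optimal_window, x$scan$optimal$log_p, col = 2, pch = 1,
         cex = 2)
  invisible(x)
}

#' @export
#' @method coef conpatch
coef.conpatch <- function(object, ...) {
  n <- nrow(object$structure$residues)
  out <- rep(NA_real_, n)
  out[object$mapping$pairs[, 2L]] <- object$scan$optimal$weighted
  out
}

#' Per-site results table
#'
#' One row per alignment column with the mapped structure residue, raw and
#' spatially weighted rate at the optimal window, distance to the anchor
#' point, and the conserved flag. Unmapped columns carry `NA` structure
#' fields.
#'
#' @param fit a [conpatch] fit.
#' @return data frame.
#' @export
site_table <- function(fit) {
  stopifnot(inherits(fit, "conpatch"))
  nc <- n_columns(fit$alignment)
  pairs <- fit$mapping$pairs
  opt <- fit$scan$optimal
  tab <- data.frame(alignment_column = seq_len(nc),
                    pdb_chain = NA_character_, pdb_resnum = NA_integer_,
                    residue = NA_character_, raw_rate = fit$rates$scores,
                    weighted_rate_at_optimal_window = NA_real_,
                    distance_to_anchor = NA_real_, is_conserved = FALSE,
                    stringsAsFactors = FALSE)
  res <- fit$structure$residues[pairs[, 2L], ]
  tab$pdb_chain[pairs[, 1L]] <- res$chain
  tab$pdb_resnum[pairs[, 1L]] <- res$resno
  tab$residue[pairs[, 1L]] <- res$aa
  tab$weighted_rate_at_optimal_window[pairs[, 1L]] <- opt$weighted
  tab$distance_to_anchor[pairs[, 1L]] <- opt$anchor_distances
  tab$is_conserved[pairs[opt$conserved, 1L]] <- TRUE
  tab
}

#' Write the per-site results table as TSV
#' @param fit a [conpatch] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(fit, path) {
  utils::write.table(site_table(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run summary as a JSON-ready list
#'
#' Contains the full configuration (including the seed) needed to
#' reproduce the run, the per-window scan, and the optimum.
#'
#' @param fit a [conpatch] fit.
#' @return nested list.
#' @export
run_summary <- function(fit) {
  stopifnot(inherits(fit, "conpatch"))
  tests <- fit$scan$tests
  list(config = fit$config,
       n_mapped = nrow(fit$mapping$pairs),
       mapping_identity = fit$mapping$identity,
       per_window = lapply(tests, function(t)
         list(w = t$window, log_p = t$log_p, t_statistic = t$t_statistic,
              anchor = unname(t$anchor))),
       optimal_window = fit$scan$optimal_window,
       log_p = fit$scan$optimal$log_p,
       significant = fit$scan$significant,
       permutation = if (!is.null(fit$permutation))
         list(n_perm = fit$permutation$n_perm,
              below_fraction = fit$permutation$below_fraction,
              log_p = fit$permutation$log_p))
}

#' Write the JSON run summary
#' @param fit a [conpatch] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(fit, path) {
  jsonlite::write_json(run_summary(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
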