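# Conserved-patch detection. Two site selections play distinct roles: the
# ANCHOR is the centroid of the sites with the lowest spatially weighted
# rates (it moves with the window size), while the TESTED GROUP is the most
# conserved fraction by raw rates (fixed across windows). The test asks
# whether the conserved group sits significantly closer to the anchor than
# the remaining sites (two-sample t-test, one-sided, Welch by default),
# scored as log_p = -ln(p); the window maximizing log_p over the
# 1-20 Angstrom scan is reported as optimal. Selecting the tested group by
# the smoothed rates instead would be badly anticonservative: the lowest
# values of any spatially smoothed field form a spatial blob even for
# i.i.d. rates, which a permutation null immediately exposes.

#' Select the most conserved sites
#'
#' Indices of the `m = round(fraction * n)` smallest values; ties at the
#' cutoff are broken by lower index.
#'
#' @param weighted numeric vector of (weighted) site rates.
#' @param fraction proportion of sites to select, in (0, 1).
#' @return sorted integer vector of selected indices.
#' @export
select_conserved <- function(weighted, fraction) {
  assert_number(fraction, "fraction", lower = 1e-12, upper = 1 - 1e-12)
  n <- length(weighted)
  m <- round(fraction * n)
  if (m < 2L)
    stop_input("protein too small for fraction %.3g (%d sites -> %d selected, need >= 2)",
               fraction, n, m)
  sort(order(weighted)[seq_len(m)])
}

#' Anchor point of the conserved sites
#'
#' The anchor is the unweighted centroid (geometric center) of the selected
#' sites' coordinates.
#'
#' @param coords n x 3 coordinate matrix.
#' @param conserved integer indices of the selected sites.
#' @return length-3 numeric vector.
#' @export
anchor_point <- function(coords, conserved) {
  coords <- as.matrix(coords)
  if (length(conserved) < 1L) stop_input("empty conserved set")
  colMeans(coords[conserved, , drop = FALSE])
}

# two-sample t (Welch by default, pooled-variance optionally);
# returns list(t, df, p) for the requested side
two_sample_t <- function(x, y, alternative = c("less", "two.sided"),
                         var_equal = FALSE) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    df <- n1 + n2 - 2
    se <- sqrt((((n1 - 1) * v1 + (n2 - 1) * v2) / df) * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (is.finite(se) && se > 0)
      se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    else n1 + n2 - 2
  }
  dm <- mean(x) - mean(y)
  if (!is.finite(se) || se == 0) {
    if (dm == 0) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    t <- ifelse(dm < 0, -Inf, Inf)
    p <- switch(alternative, less = ifelse(dm < 0, 0, 1), two.sided = 0)
    return(list(t = t, df = df, p = p, degenerate = FALSE))
  }
  t <- dm / se
  p <- switch(alternative,
              less = stats::pt(t, df),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p, degenerate = FALSE)
}

# backward-compatible pooled-variance wrapper
pooled_t_test <- function(x, y, alternative = c("less", "two.sided")) {
  two_sample_t(x, y, alternative, var_equal = TRUE)
}

#' Test for a conserved patch at one window size
#'
#' Anchors on the centroid of the most conserved `fraction` of sites by the
#' spatially weighted rates, then compares the Euclidean distances to that
#' anchor of the most conserved fraction by the `raw` rates against those of
#' the remaining sites with a two-sample Student's t-test (one-sided,
#' conserved closer; Welch by default, since the tested group is usually
#' far more homogeneous than the remainder). When `raw` is omitted the weighted rates
#' define both selections (useful for single-score tests, but
#' anticonservative inside a window scan -- see Details). The p-value is
#' floored at 1e-320 so that `log_p = -ln(p)` stays finite; if all
#' distances are identical (zero pooled variance) the test is degenerate
#' and `p = 1` with a warning.
#'
#' @details Defining the tested group by the smoothed rates would select a
#'   spatially contiguous blob even for random rates (the minima of any
#'   smoothed field cluster in space), so the permutation null of the scan
#'   is only calibrated when the group comes from the raw rates while the
#'   anchor tracks the smoothed field.
#'
#' @param coords n x 3 coordinate matrix.
#' @param weighted weighted rates from [weighted_rates()] (lower = more
#'   conserved); defines the anchor.
#' @param raw raw (unsmoothed) site rates defining the tested group;
#'   defaults to `weighted`.
#' @param fraction proportion of sites defining the conserved set
#'   (default 0.10).
#' @param alternative `"less"` (one-sided, default) or `"two.sided"`.
#' @param var_equal use the pooled-variance (classic Student) statistic
#'   instead of Welch (default FALSE).
#' @return An object of class `patch_test`: list with `window`, `anchor`,
#'   `anchor_set`, `conserved` (the tested group), `t_statistic`, `df`,
#'   `p_value`, `log_p`.
#' @export
patch_test <- function(coords, weighted, raw = NULL, fraction = 0.10,
                       alternative = c("less", "two.sided"),
                       var_equal = FALSE) {
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(weighted) != n)
    stop_input("weighted rates (%d) and coordinates (%d) do not match",
               length(weighted), n)
  raw <- raw %||% weighted
  if (length(raw) != n)
    stop_input("raw rates (%d) and coordinates (%d) do not match",
               length(raw), n)
  anchor_set <- select_conserved(weighted, fraction)
  conserved <- select_conserved(raw, fraction)
  if (n < length(conserved) + 2L)
    stop_input("too few remaining sites for the t-test")
  anchor <- anchor_point(coords, anchor_set)
  dist_all <- sqrt(colSums((t(coords) - anchor)^2))
  tt <- two_sample_t(dist_all[conserved], dist_all[-conserved], alternative,
                     var_equal = var_equal)
  if (tt$degenerate)
    warning("all anchor distances identical; patch test is degenerate (p = 1)")
  p <- max(tt$p, 1e-320)
  structure(list(window = attr(weighted, "window"), anchor = anchor,
                 anchor_set = anchor_set, conserved = conserved,
                 t_statistic = tt$t, df = tt$df,
                 p_value = p, log_p = -log(p),
                 anchor_distances = dist_all, fraction = fraction),
            class = "patch_test")
}

#' @export
print.patch_test <- function(x, ...) {
  cat(sprintf("Patch test%s: %d conserved sites, t = %.3f, log P = %.2f\n",
              if (!is.null(x$window)) sprintf(" (window %g A)", x$window) else "",
              length(x$conserved), x$t_statistic, x$log_p))
  invisible(x)
}

#' Scan window sizes for the strongest conserved patch
#'
#' Runs the weighting + anchor + t-test cascade for each window size and
#' reports the window maximizing `log_p = -ln(p)`; ties go to the smallest
#' window (least smoothing). A patch is called significant when the optimal
#' `log_p` reaches the threshold (default 8, i.e. p <= exp(-8)).
#'
#' @param rates numeric vector of raw site rates for the mapped residues.
#' @param coords n x 3 coordinate matrix for the same residues.
#' @param dmat optional precomputed distance matrix.
#' @param w_min,w_max,step window scan range in Angstroms (default 1-20, 1).
#' @param fraction conserved fraction (default 0.10).
#' @param threshold significance threshold on `log_p` (default 8).
#' @param alternative t-test sidedness, see [patch_test()].
#' @param var_equal pooled-variance t instead of Welch (default FALSE).
#' @return An object of class `patch_scan`: per-window table, the list of
#'   `patch_test` objects, `optimal_window`, `optimal` test, `significant`.
#' @export
scan_windows <- function(rates, coords, dmat = NULL, w_min = 1, w_max = 20,
                         step = 1, fraction = 0.10, threshold = 8,
                         alternative = c("less", "two.sided"),
                         var_equal = FALSE) {
  alternative <- match.arg(alternative)
  if (w_min < 1 || w_max < w_min || step <= 0)
    stop_input("invalid window range [%g, %g] step %g", w_min, w_max, step)
  coords <- as.matrix(coords)
  dmat <- dmat %||% distance_matrix(coords)
  windows <- seq(w_min, w_max, by = step)
  tests <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    wr <- weighted_rates(rates, dmat, windows[i])
    tests[[i]] <- suppressWarnings(
      patch_test(coords, wr, raw = rates, fraction = fraction,
                 alternative = alternative, var_equal = var_equal))
    tests[[i]]$weighted <- wr
  }
  log_p <- vapply(tests, function(t) t$log_p, numeric(1))
  opt <- which.max(log_p)   # first max = smallest window on ties
  tab <- data.frame(window = windows,
                    t_statistic = vapply(tests, `[[`, numeric(1), "t_statistic"),
                    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
                    log_p = log_p,
                    n_conserved = vapply(tests, function(t) length(t$conserved),
                                         integer(1)))
  structure(list(table = tab, tests = tests,
                 optimal_window = windows[opt], optimal = tests[[opt]],
                 significant = log_p[opt] >= threshold,
                 threshold = threshold, fraction = fraction,
                 alternative = alternative),
            class = "patch_scan")
}

#' @export
print.patch_scan <- function(x, ...) {
  cat(sprintf("Window scan (%g-%g A, fraction %.2f): optimal %g A, log P = %.2f (%s)\n",
              min(x$table$window), max(x$table$window), x$fraction,
              x$optimal_window, x$optimal$log_p,
              if (x$significant) sprintf("significant at threshold %g", x$threshold)
              else "not significant"))
  invisible(x)
}

#' Permutation null for the window scan
#'
#' Randomly permutes the raw site-rate vector across residues (destroying
#' any spatial clustering at its source), reruns the full weighting + scan
#' per replicate, and reports how often the optimal `log_p` reaches the
#' significance threshold.
#'
#' @inheritParams scan_windows
#' @param n_perm number of permutation replicates (default 100).
#' @param seed RNG seed for reproducibility.
#' @param var_equal pooled-variance t instead of Welch (default FALSE).
#' @return list with `log_p` (per-replicate optima), `exceedance` (fraction
#'   `>= threshold`), `below_fraction`, `n_perm`, `seed`.
#' @export
permutation_null <- function(rates, coords, dmat = NULL, n_perm = 100L,
                             seed = NULL, fraction = 0.10, threshold = 8,
                             w_min = 1, w_max = 20, step = 1,
                             alternative = c("less", "two.sided"),
                             var_equal = FALSE) {
  alternative <- match.arg(alternative)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  coords <- as.matrix(coords)
  dmat <- dmat %||% distance_matrix(coords)
  lp <- vapply(seq_len(n_perm), function(i) {
    sc <- scan_windows(sample(rates), coords, dmat, w_min = w_min,
                       w_max = w_max, step = step, fraction = fraction,
                       threshold = threshold, alternative = alternative,
                       var_equal = var_equal)
    sc$optimal$log_p
  }, numeric(1))
  list(log_p = lp, exceedance = mean(lp >= threshold),
       below_fraction = mean(lp < threshold), n_perm = n_perm, seed = seed)
}

#' Scan across conserved-fraction settings
#'
#' Repeats the window scan for a range of conserved fractions (default 5%
#' to 25% in 5% steps). Fractions too small for the protein are reported as
#' errors without stopping the sweep.
#'
#' @inheritParams scan_windows
#' @param fractions fractions to test (default `seq(0.05, 0.25, 0.05)`).
#' @param var_equal pooled-variance t instead of Welch (default FALSE).
#' @return list with `results` (per-fraction `patch_scan` or condition) and
#'   `table` (fraction, optimal window, log_p, significant).
#' @export
fraction_sweep <- function(rates, coords, dmat = NULL,
                           fractions = seq(0.05, 0.25, by = 0.05),
                           w_min = 1, w_max = 20, step = 1, threshold = 8,
                           alternative = c("less", "two.sided"),
                           var_equal = FALSE) {
  alternative <- match.arg(alternative)
  coords <- as.matrix(coords)
  dmat <- dmat %||% distance_matrix(coords)
  res <- lapply(fractions, function(f) {
    tryCatch(scan_windows(rates, coords, dmat, w_min = w_min, w_max = w_max,
                          step = step, fraction = f, threshold = threshold,
                          alternative = alternative, var_equal = var_equal),
             conpatch_input_error = function(e) e)
  })
  tab <- data.frame(
    fraction = fractions,
    optimal_window = vapply(res, function(r)
      if (inherits(r, "patch_scan")) r$optimal_window else NA_real_, numeric(1)),
    log_p = vapply(res, function(r)
      if (inherits(r, "patch_scan")) r$optimal$log_p else NA_real_, numeric(1)),
    significant = vapply(res, function(r)
      if (inherits(r, "patch_scan")) r$significant else NA, logical(1)),
    error = vapply(res, function(r)
      if (inherits(r, "condition")) conditionMessage(r) else "", character(1)))
  list(results = res, table = tab)
}
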