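# Site-specific substitution rates: Poisson-corrected distances, a
# neighbor-joining guide tree, a discretized-gamma rate prior whose shape is
# fitted by maximum likelihood on a grid, and empirical-Bayes posterior-mean
# rates per alignment column. Scores are z-normalized so that lower values
# mean stronger conservation.

new_site_rates <- function(scores, provenance, normalization, raw = NULL,
                           shape = NULL, tree = NULL, model = NULL,
                           residues = NULL) {
  structure(list(scores = as.numeric(scores), provenance = provenance,
                 normalization = normalization, raw = raw, shape = shape,
                 tree = tree, model = model, residues = residues),
            class = "site_rates")
}

#' @export
print.site_rates <- function(x, ...) {
  cat(sprintf("Site rates: %d columns (%s%s)\n", length(x$scores),
              x$provenance,
              if (!is.null(x$shape)) sprintf(", gamma shape %.3f", x$shape) else ""))
  invisible(x)
}

#' Poisson-corrected pairwise distances
#'
#' Distance between two aligned sequences is `d = -ln(1 - p)` with `p` the
#' mismatch proportion over columns where neither sequence has a gap or
#' unknown residue; `p >= 0.95` saturates to `d = 3`.
#'
#' @param aln an [aa_alignment] with at least two sequences.
#' @return symmetric numeric matrix of distances with the sequence ids as
#'   dimnames.
#' @export
pairwise_distance <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  m <- alignment_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop_input("need at least 2 sequences for distances")
  obs <- m > 0L
  # matches via per-state indicator cross products (gaps drop out)
  match_mat <- matrix(0, n, n)
  for (a in seq_len(20L)) {
    ia <- m == a
    if (any(ia)) match_mat <- match_mat + tcrossprod(ia * 1)
  }
  overlap <- tcrossprod(obs * 1)
  if (any(overlap[upper.tri(overlap)] == 0)) {
    bad <- which(overlap == 0 & upper.tri(overlap), arr.ind = TRUE)[1L, ]
    stop_input("sequences '%s' and '%s' share no gap-free columns",
               aln$ids[bad[1L]], aln$ids[bad[2L]])
  }
  p <- (overlap - match_mat) / overlap
  d <- ifelse(p >= 0.95, 3, -log(1 - p))
  diag(d) <- 0
  dimnames(d) <- list(aln$ids, aln$ids)
  d
}

#' Neighbor-joining guide tree
#'
#' Standard neighbor joining with the usual fix for negative branch
#' lengths: a negative length is transferred to its sibling branch (so the
#' distance between the two children is preserved) and clamped at zero.
#'
#' @param dist symmetric distance matrix with taxon names as dimnames.
#' @param ids optional taxon names overriding the dimnames.
#' @return an `ape` `phylo` tree (unrooted).
#' @export
build_nj_tree <- function(dist, ids = NULL) {
  dist <- as.matrix(dist)
  if (!is.null(ids)) dimnames(dist) <- list(ids, ids)
  if (nrow(dist) < 3L) stop_input("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(dist)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    par <- tr$edge[e, 1L]
    sib <- which(tr$edge[, 1L] == par)
    sib <- sib[sib != e]
    if (length(sib)) {
      s <- sib[1L]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Discrete-gamma category rates (mean of bin)
#'
#' Divides a mean-one gamma distribution into `k` equal-probability bins and
#' represents each by its conditional mean, so the representatives average
#' exactly to one.
#'
#' @param shape gamma shape parameter (> 0).
#' @param k number of categories (default 16).
#' @return numeric vector of `k` category rates.
#' @export
gamma_category_rates <- function(shape, k = 16L) {
  assert_number(shape, "shape", lower = 1e-8)
  k <- as.integer(k)
  if (k < 1L) stop_input("k must be >= 1")
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  r <- k * diff(stats::pgamma(q, shape = shape + 1, rate = shape))
  r / mean(r)
}

# reversible rate matrix + its eigensystem for a named model and frequencies
substitution_model <- function(model = c("JTT", "LG"), freqs = NULL) {
  model <- match.arg(model)
  exch <- if (model == "JTT") .JTT_EXCH else .LG_EXCH
  freqs <- freqs %||% (if (model == "JTT") .JTT_FREQ else .LG_FREQ)
  freqs <- freqs / sum(freqs)
  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- exch
  S <- S + t(S)
  Q <- S * rep(freqs, each = 20L)       # Q[i,j] = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(freqs * -diag(Q))        # one expected substitution per unit time
  sp <- sqrt(freqs)
  B <- Q * (sp %o% (1 / sp))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(name = model, freqs = freqs, Q = Q,
       U = eig$vectors / sp, Uinv = t(eig$vectors) * rep(sp, each = 20L),
       lambda = eig$values)
}

# per-site per-category log-likelihoods on a tree (C++ pruning);
# tipmat is n_columns x n_tips with tips ordered as tree$tip.label
site_category_loglik <- function(tipmat, tree, sm, rates) {
  tr <- ape::reorder.phylo(tree, "postorder")
  site_loglik_cpp(tipmat, tr$edge, tr$edge.length,
                  length(tr$tip.label) + tr$Nnode,
                  sm$U, sm$Uinv, sm$lambda, sm$freqs, rates)
}

check_tree_alignment <- function(aln, tree) {
  if (!inherits(tree, "phylo")) stop_input("tree must be a 'phylo' object")
  if (!setequal(tree$tip.label, aln$ids))
    stop_input("tree tip labels do not match alignment ids")
  if (is.null(tree$edge.length)) stop_input("tree has no branch lengths")
}

# tip matrix with columns ordered as tree tip labels
tips_for_tree <- function(aln, tree) {
  m <- alignment_matrix(aln)
  t(m[match(tree$tip.label, aln$ids), , drop = FALSE])  # n_col x n_tip
}

#' Fit the gamma shape of among-site rate variation
#'
#' Grid search for the gamma shape maximizing the alignment log-likelihood
#' under a discretized mean-one gamma prior over site rates (uniform
#' category weights), with column likelihoods computed by Felsenstein
#' pruning under a reversible amino-acid replacement model.
#'
#' @param aln an [aa_alignment] (>= 3 sequences).
#' @param tree a `phylo` tree whose tips match the alignment ids.
#' @param grid candidate shape values (default 40 log-spaced points in
#'   `[0.05, 5]`).
#' @param k number of discrete gamma categories (default 16).
#' @param model `"JTT"` (default) or `"LG"`.
#' @param frequencies `"empirical"` (default; counts from the alignment
#'   with a pseudocount) or `"model"`.
#' @return An object of class `gamma_model`: list with `shape`, `k`,
#'   `category_rates`, `loglik`, the searched `grid` and `grid_loglik`, and
#'   the cached per-site per-category log-likelihood matrix at the fitted
#'   shape (`site_loglik`).
#' @export
fit_gamma_shape <- function(aln, tree, grid = NULL, k = 16L,
                            model = c("JTT", "LG"),
                            frequencies = c("empirical", "model")) {
  model <- match.arg(model); frequencies <- match.arg(frequencies)
  grid <- grid %||% exp(seq(log(0.05), log(5), length.out = 40L))
  if (length(grid) < 1L || any(grid <= 0)) stop_input("invalid shape grid")
  check_tree_alignment(aln, tree)
  if (length(aln$seqs) < 3L) stop_input("need >= 3 sequences to fit rates")
  sm <- substitution_model(model,
                           if (frequencies == "empirical") empirical_frequencies(aln))
  tipmat <- tips_for_tree(aln, tree)   # n_col x n_tip
  best <- NULL
  gll <- rep(NA_real_, length(grid))
  for (gi in seq_along(grid)) {
    rates <- gamma_category_rates(grid[gi], k)
    sl <- site_category_loglik(tipmat, tree, sm, rates)
    ll <- sum(row_logsumexp(sl)) - nrow(tipmat) * log(k)
    gll[gi] <- ll
    if (is.finite(ll) && (is.null(best) || ll > best$loglik))
      best <- list(shape = grid[gi], loglik = ll, rates = rates, sl = sl)
  }
  if (is.null(best))
    stop_compute("log-likelihood is -Inf over the whole shape grid (degenerate alignment)")
  structure(list(shape = best$shape, k = k, category_rates = best$rates,
                 loglik = best$loglik, grid = grid, grid_loglik = gll,
                 model = model, frequencies = frequencies,
                 site_loglik = best$sl),
            class = "gamma_model")
}

#' @export
print.gamma_model <- function(x, ...) {
  cat(sprintf("Discrete gamma model: shape %.4f, %d categories (logLik %.2f, %s)\n",
              x$shape, x$k, x$loglik, x$model))
  invisible(x)
}

#' Empirical-Bayes posterior-mean site rates
#'
#' For each alignment column computes the posterior mean rate
#' `E[r | column] = sum_c r_c L(col | r_c) / sum_c L(col | r_c)` over the
#' discrete gamma categories (uniform prior), treating gaps and `X` as
#' missing data. Raw posterior means are then z-normalized over columns
#' (lower = more conserved); if the standard deviation is zero all scores
#' are zero. Columns with no observed residues (or a numerically zero
#' likelihood in every category) get score 0 with a warning. Per-site error
#' estimates are deliberately not produced.
#'
#' @param aln an [aa_alignment].
#' @param tree a `phylo` tree whose tips match the alignment ids.
#' @param model a `gamma_model` from [fit_gamma_shape()].
#' @param use_cache reuse the model's cached per-site likelihood matrix when
#'   its dimensions match (default TRUE).
#' @return A `site_rates` object with `provenance = "internal"`; `$raw`
#'   holds the unnormalized posterior means.
#' @export
site_rates_empirical_bayes <- function(aln, tree, model, use_cache = TRUE) {
  stopifnot(inherits(model, "gamma_model"))
  check_tree_alignment(aln, tree)
  tipmat <- tips_for_tree(aln, tree)
  nc <- n_columns(aln)
  sl <- model$site_loglik
  if (!use_cache || is.null(sl) || nrow(sl) != nc) {
    sm <- substitution_model(model$model,
                             if (model$frequencies == "empirical") empirical_frequencies(aln))
    sl <- site_category_loglik(tipmat, tree, sm, model$category_rates)
  }
  mx <- apply(sl, 1L, max)
  w <- exp(sl - ifelse(is.finite(mx), mx, 0))
  post <- as.numeric(w %*% model$category_rates) / rowSums(w)
  bad <- !is.finite(post) | rowSums(tipmat > 0L) == 0L
  if (any(bad)) {
    warning(sprintf("%d column(s) carry no information; score set to 0", sum(bad)))
    post[bad] <- NA_real_
  }
  s <- stats::sd(post, na.rm = TRUE)
  z <- if (!is.finite(s) || s == 0) rep(0, nc)
       else (post - mean(post, na.rm = TRUE)) / s
  z[bad] <- 0
  new_site_rates(z, provenance = "internal", normalization = "zscored",
                 raw = post, shape = model$shape, tree = tree,
                 model = model$model)
}

#' Estimate site-specific substitution rates from an alignment
#'
#' One-call rate estimation: Poisson-corrected distances, neighbor-joining
#' guide tree (unless one is supplied), gamma-shape fit on a grid, and
#' empirical-Bayes posterior-mean rates, z-normalized.
#'
#' @inheritParams fit_gamma_shape
#' @param tree optional user tree (`phylo`); inferred by neighbor joining
#'   when `NULL`.
#' @return A `site_rates` object (`provenance = "internal"`).
#' @export
site_rates <- function(aln, tree = NULL, grid = NULL, k = 16L,
                       model = c("JTT", "LG"),
                       frequencies = c("empirical", "model")) {
  if (is.null(tree)) tree <- build_nj_tree(pairwise_distance(aln))
  gm <- fit_gamma_shape(aln, tree, grid = grid, k = k, model = model,
                        frequencies = frequencies)
  site_rates_empirical_bayes(aln, tree, gm)
}
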