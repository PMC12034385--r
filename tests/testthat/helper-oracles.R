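# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: brute-force loops, Matrix::expm instead
# of the package's eigendecomposition, and textbook formulas.

# Eq-style distance-weighted mean, naive double loop
brute_weighted_rates <- function(rates, coords, window) {
  n <- length(rates)
  out <- numeric(n)
  for (a in seq_len(n)) {
    acc <- 0; nn <- 0
    for (i in seq_len(n)) {
      d <- sqrt(sum((coords[a, ] - coords[i, ])^2))
      if (d <= window) {
        nn <- nn + 1
        acc <- acc + if (d == 0) rates[i] else rates[i] / d
      }
    }
    out[a] <- acc / nn
  }
  out
}

# textbook pooled-variance two-sample t, one-sided "x smaller"
brute_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = pt(t, n1 + n2 - 2))
}

# single-site pruning likelihood with Matrix::expm (independent of the
# package's eigen route and of its C++ traversal)
brute_site_lik <- function(tree, states, Q, freqs, rate = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  L <- matrix(1, n_tip + tr$Nnode, 20)
  for (i in seq_len(n_tip)) {
    s <- states[tr$tip.label[i]]
    if (s > 0) { L[i, ] <- 0; L[i, s] <- 1 }
  }
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    P <- as.matrix(Matrix::expm(Q * (tr$edge.length[e] * rate)))
    L[pa, ] <- L[pa, ] * as.numeric(P %*% L[ch, ])
  }
  sum(freqs * L[n_tip + 1L, ])
}

# random compact-ish point cloud for spatial tests
random_coords <- function(n, scale = 10) matrix(runif(n * 3, 0, scale), n, 3)

aa_codes <- function(s) match(strsplit(s, "")[[1]], strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
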