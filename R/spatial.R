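#' Euclidean distance matrix of residue coordinates
#'
#' @param coords numeric matrix (n x 3) of coordinates in Angstroms.
#' @return symmetric n x n matrix of Euclidean distances (zero diagonal).
#' @export
distance_matrix <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L || ncol(coords) != 3L)
    stop_input("coords must be an n x 3 matrix with n >= 1")
  if (!all(is.finite(coords))) stop_input("non-finite coordinates")
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  d
}

#' Spatially correlated (distance-weighted) site rates
#'
#' For each focal residue `A`, averages the rates of all residues within
#' the window (closed boundary, the focal residue included) with
#' distance-discounted weights:
#' `S_bar(A) = (1/N) * sum_i [ S_i  if d_Ai = 0 ;  S_i / d_Ai  otherwise ]`,
#' where `N` is the neighborhood size. Note the division is by `N`, not by
#' the sum of weights, so this is not a conventional weighted mean: sites
#' whose neighbors are mostly distant shrink toward zero. Residues at
#' coincident coordinates (distance exactly 0) contribute their unweighted
#' rate, so no division by zero can occur.
#'
#' @param rates numeric vector of site rates, one per residue, aligned with
#'   `dmat`.
#' @param dmat distance matrix from [distance_matrix()].
#' @param window neighborhood radius in Angstroms (> 0).
#' @return numeric vector of weighted rates with attributes `window` and
#'   `n_neighbors`.
#' @export
weighted_rates <- function(rates, dmat, window) {
  assert_number(window, "window", lower = .Machine$double.eps)
  dmat <- as.matrix(dmat)
  n <- length(rates)
  if (nrow(dmat) != n || ncol(dmat) != n)
    stop_input("rates (%d) and distance matrix (%dx%d) do not match",
               n, nrow(dmat), ncol(dmat))
  inside <- dmat <= window
  w <- 1 / dmat
  w[dmat == 0] <- 1
  out <- as.numeric((inside * w) %*% rates) / rowSums(inside)
  attr(out, "window") <- window
  attr(out, "n_neighbors") <- rowSums(inside)
  out
}
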