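#' Normalised Hamming similarity between two allocations
#'
#' \eqn{S(D, E) = \frac{1}{NM}\sum_i (M - \mathrm{hamm}(D_i, E_i))}, where
#' \eqn{\mathrm{hamm}(D_i, E_i)} counts the pathway columns in which the
#' rows for gene \eqn{i} differ. Equivalently
#' \eqn{S = 1 - d(D,E)/(NM)} with \eqn{d} the total Hamming distance.
#' `S = 1` iff the allocations are identical; identical rows contribute the
#' full weight `M` each.
#'
#' @inheritParams allocation_distance
#' @return A number in `[0, 1]`.
#' @export
hamming_similarity <- function(a, b) {
  a <- as_allocation_matrix(a)
  b <- as_allocation_matrix(b)
  if (!all(dim(a) == dim(b))) abort("allocations must have identical dimensions.")
  1 - sum(abs(a - b)) / (nrow(a) * ncol(a))
}

#' Fuzzy adjusted Rand index between two allocations
#'
#' Measures whether the two allocations place the same gene pairs together
#' in (some) common pathway, correcting for chance agreement. Because a
#' multi-membership gene may be allocated to several pathways at once, each
#' allocation is first read as a fuzzy partition: gene \eqn{g} gets
#' membership degree \eqn{1/|\mathrm{row}_g|} in each pathway it is
#' allocated to (equal weights) and 0 elsewhere. For a gene pair the
#' co-membership degree is
#' \eqn{\psi(g, g') = \sum_k \min(u_{gk}, u_{g'k}) \in [0, 1]}. Treating
#' "allocated together" as the fuzzy set of pairs with weight \eqn{\psi},
#' the four pair counts of the Rand family become fuzzy cardinalities
#' (\eqn{a = \sum \min(\psi_D, \psi_E)}, \eqn{b, c} the one-sided
#' differences, \eqn{d = \sum \min(1 - \psi_D, 1 - \psi_E)}) and the index
#' is the pair-counting form of the adjusted Rand index,
#' \eqn{2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d))}.
#'
#' The index is 1 exactly for identical allocations, reduces to the
#' classical adjusted Rand index when every gene is allocated to a single
#' pathway (crisp case), is invariant to consistent pathway relabelling,
#' and has expectation near 0 for independent random allocations. Unlike
#' [hamming_similarity()], it stays high when whole groups of genes are
#' kept together but swapped into different pathways.
#'
#' Only genes allocated somewhere in both allocations are compared; a gene
#' allocated in one but not the other is an error.
#'
#' @inheritParams allocation_distance
#' @return A number `<= 1`, with attribute `variant` recording the fuzzy
#'   extension used.
#' @export
fuzzy_rand_index <- function(a, b) {
  a <- as_allocation_matrix(a)
  b <- as_allocation_matrix(b)
  if (!all(dim(a) == dim(b))) abort("allocations must have identical dimensions.")
  ra <- rowSums(a)
  rb <- rowSums(b)
  if (any(xor(ra > 0, rb > 0))) {
    abort("a gene is allocated in one allocation but nowhere in the other.")
  }
  keep <- ra > 0
  if (sum(keep) < 2L) abort("need at least two allocated genes to compare.")
  ua <- a[keep, , drop = FALSE] / ra[keep]
  ub <- b[keep, , drop = FALSE] / rb[keep]
  psi_a <- pairwise_comembership(ua)
  psi_b <- pairwise_comembership(ub)
  ut <- upper.tri(psi_a)
  pa <- psi_a[ut]
  pb <- psi_b[ut]
  A <- sum(pmin(pa, pb))
  B <- sum(pmax(pa - pb, 0))
  C <- sum(pmax(pb - pa, 0))
  D <- sum(pmin(1 - pa, 1 - pb))
  denom <- (A + B) * (B + D) + (A + C) * (C + D)
  value <- if (denom == 0) {
    # degenerate: all pairs together (or all apart) in both partitions
    if (B == 0 && C == 0) 1 else 0
  } else {
    2 * (A * D - B * C) / denom
  }
  structure(value, variant = "pair-counting, min-intersection, equal weights")
}

# psi[g, g'] = sum_k min(u[g, k], u[g', k])
pairwise_comembership <- function(u) {
  n <- nrow(u)
  psi <- matrix(0, n, n)
  for (k in seq_len(ncol(u))) {
    col <- u[, k]
    if (all(col == 0)) next
    psi <- psi + outer(col, col, pmin)
  }
  psi
}
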