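#' Exact Hamming-distance null for one multi-membership gene
#'
#' The distribution of the Hamming distance between two independent,
#' uniformly random valid allocations of a gene that belongs to `n`
#' pathways. A valid allocation row is any of the \eqn{2^n - 1} nonzero
#' binary strings, so there are \eqn{(2^n - 1)^2} ordered pairs. The count
#' of pairs at distance 0 is \eqn{2^n - 1}; at distance \eqn{r \ge 1} it is
#' \eqn{\binom{n}{r}(2^n - 2)}: choose the differing positions, choose the
#' first string freely among \eqn{2^n} (the second is then determined), and
#' discard the two pairs in which either string is all-zero. The counts are
#' exact integers and sum to \eqn{(2^n - 1)^2}.
#'
#' @param n_pathways Number of pathways the gene belongs to (`n >= 1`).
#' @return A `hamming_null` object: tibble with columns `distance`,
#'   `count`, `probability`; attributes `n_genes` and `total_pairs`.
#' @examples
#' hamming_null(2)  # probabilities 3/9, 4/9, 2/9
#' @export
hamming_null <- function(n_pathways) {
  if (!is.numeric(n_pathways) || length(n_pathways) != 1L || n_pathways < 1 ||
      n_pathways != round(n_pathways)) {
    abort("`n_pathways` must be a single integer >= 1.")
  }
  n <- as.numeric(n_pathways)
  valid <- 2^n - 1
  counts <- c(valid, choose(n, seq_len(n)) * (2^n - 2))
  total <- valid^2
  new_hamming_null(
    counts = counts,
    total = total,
    n_genes = 1L
  )
}

new_hamming_null <- function(counts, total, n_genes) {
  tbl <- tibble::tibble(
    distance = seq_along(counts) - 1L,
    count = counts,
    probability = counts / total
  )
  structure(tbl,
    class = c("hamming_null", class(tbl)),
    n_genes = n_genes,
    total_pairs = total
  )
}

# plain convolution of two nonnegative weight vectors indexed from 0
conv_counts <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Combine per-gene Hamming nulls across genes
#'
#' The total Hamming distance between two allocations is the sum of the
#' independent per-gene distances, so the combined null is the convolution
#' of the per-gene distributions — the sequential merge-and-expand that
#' avoids building the full cross-product table. Convolution is
#' associative and commutative, so gene order does not matter.
#'
#' @param nulls A list of `hamming_null` objects (or several passed via
#'   `...`).
#' @param ... Additional `hamming_null` objects.
#' @return A `hamming_null` over distances `0..sum(max distances)`.
#' @examples
#' g <- hamming_null(2)
#' combine_hamming_nulls(g, g)  # the two-gene combined null
#' @export
combine_hamming_nulls <- function(nulls, ...) {
  if (inherits(nulls, "hamming_null")) nulls <- list(nulls)
  nulls <- c(nulls, list(...))
  if (length(nulls) == 0L) abort("need at least one null distribution.")
  ok <- vapply(nulls, inherits, logical(1L), "hamming_null")
  if (!all(ok)) abort("all inputs must be `hamming_null` objects.")
  counts <- nulls[[1L]]$count
  total <- attr(nulls[[1L]], "total_pairs")
  n_genes <- attr(nulls[[1L]], "n_genes")
  for (k in seq_along(nulls)[-1L]) {
    counts <- conv_counts(counts, nulls[[k]]$count)
    total <- total * attr(nulls[[k]], "total_pairs")
    n_genes <- n_genes + attr(nulls[[k]], "n_genes")
  }
  new_hamming_null(counts, total, n_genes)
}

#' Exact Hamming null for a whole membership/expression instance
#'
#' Builds the per-gene null for every expressed multi-membership gene and
#' convolves them. Expressed single-membership genes have a fixed row
#' (distance always 0) and stable genes are never allocated, so neither
#' contributes. With no free gene the null is a point mass at distance 0.
#'
#' @inheritParams full_allocation
#' @return A `hamming_null`.
#' @export
allocation_null <- function(membership, states) {
  x <- state_vector(states, membership)
  free <- x != 0L & membership$n_members > 1L
  if (!any(free)) {
    return(new_hamming_null(counts = 1, total = 1, n_genes = 0L))
  }
  nulls <- lapply(membership$n_members[free], hamming_null)
  combine_hamming_nulls(nulls)
}

#' Tail probability of an observed Hamming distance under the null
#'
#' Lower-tail by default: the probability that two uniformly random valid
#' allocations are at least as close (distance `<= observed`) as the pair
#' in hand — small values mean the observed agreement is better than
#' chance. `lower = FALSE` gives the complementary question (at least as
#' far apart).
#'
#' @param null A `hamming_null`.
#' @param observed Integer distance within the null's support.
#' @param lower Use the lower tail (default) or the upper tail.
#' @return A probability, computed from the exact integer counts.
#' @export
null_tail_probability <- function(null, observed, lower = TRUE) {
  if (!inherits(null, "hamming_null")) abort("`null` must be a `hamming_null`.")
  r_max <- max(null$distance)
  if (!is.numeric(observed) || length(observed) != 1L ||
      observed != round(observed) || observed < 0 || observed > r_max) {
    abort(sprintf("`observed` must be an integer in [0, %d].", r_max))
  }
  total <- attr(null, "total_pairs")
  if (lower) {
    sum(null$count[null$distance <= observed]) / total
  } else {
    sum(null$count[null$distance >= observed]) / total
  }
}

#' @export
print.hamming_null <- function(x, ...) {
  cat(sprintf(
    "<hamming_null> %d gene(s), distances 0..%d, %g ordered pairs\n",
    attr(x, "n_genes"), max(x$distance), attr(x, "total_pairs")
  ))
  NextMethod()
}
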