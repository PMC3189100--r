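#' Full-membership allocation of expressed genes
#'
#' The allocation in which every expressed gene is kept in all of its member
#' pathways — the picture drawn by conventional pathway visualisation, and
#' the reference point the searches start improving on. Stable genes carry
#' all-zero rows: they take no part in the allocation problem.
#'
#' @param membership A [pathway_membership()].
#' @param states Output of [gene_states()] (or a named state vector).
#' @return Integer genes-by-pathways allocation matrix.
#' @export
full_allocation <- function(membership, states) {
  x <- state_vector(states, membership)
  A <- membership$incidence
  A[x == 0L, ] <- 0L
  A
}

#' Validity of a gene-to-pathway allocation
#'
#' An allocation `A` is valid when (i) it never contradicts the membership
#' snapshot (`A` is entrywise at most `P`), (ii) every expressed gene is
#' allocated to at least one pathway, (iii) expressed single-membership
#' genes keep their (only) membership, (iv) stable genes are allocated
#' nowhere, and (v) in module mode no gene occupies both members of an
#' opposing pair.
#'
#' @param alloc Integer allocation matrix aligned to `membership`.
#' @inheritParams full_allocation
#' @param opposing Optional two-column data frame of opposing module pairs.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_allocation <- function(alloc, membership, states, opposing = NULL) {
  P <- membership$incidence
  if (!is.matrix(alloc) || !all(dim(alloc) == dim(P))) {
    abort("`alloc` must be a matrix with the membership's dimensions.")
  }
  x <- state_vector(states, membership)
  if (!all(alloc %in% c(0L, 1L))) return(FALSE)
  if (any(alloc == 1L & P == 0L)) return(FALSE)
  expressed <- x != 0L
  rs <- rowSums(alloc)
  if (any(rs[expressed] < 1L)) return(FALSE)
  if (any(rs[!expressed] > 0L)) return(FALSE)
  single <- expressed & membership$n_members == 1L
  if (any(alloc[single, , drop = FALSE] != P[single, , drop = FALSE])) {
    return(FALSE)
  }
  pairs <- check_opposing(opposing, membership)
  if (nrow(pairs) > 0L) {
    ja <- match(pairs[, 1L], membership$pathways)
    jb <- match(pairs[, 2L], membership$pathways)
    for (k in seq_along(ja)) {
      if (any(alloc[, ja[k]] * alloc[, jb[k]] == 1L)) return(FALSE)
    }
  }
  TRUE
}

# Draw a uniformly random nonzero binary row over `members` (pathway column
# indices). Uniform over the 2^n - 1 admissible strings.
random_row <- function(members) {
  n <- length(members)
  k <- sample.int(2L^n - 1L, 1L)  # 1 .. 2^n - 1, never the all-zero string
  bits <- as.integer(intToBits(k)[seq_len(n)])
  members[bits == 1L]
}

#' Random valid allocation
#'
#' Draws an independent uniformly random valid row for every expressed
#' multi-membership gene: each of the \eqn{2^n - 1} nonzero binary strings
#' over its \eqn{n} member pathways is equally likely, matching the null
#' model used for the exact Hamming-distance distribution. Expressed
#' single-membership genes keep their membership; stable genes get all-zero
#' rows. In module mode, rows violating an opposing pair are resampled until
#' valid, which preserves uniformity over the admissible strings.
#'
#' @inheritParams is_valid_allocation
#' @param seed Optional integer seed for reproducibility.
#' @return Integer allocation matrix.
#' @export
random_allocation <- function(membership, states, opposing = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- state_vector(states, membership)
  pairs <- check_opposing(opposing, membership)
  opp <- opposing_index(membership, pairs)
  P <- membership$incidence
  A <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  expressed <- which(x != 0L)
  for (i in expressed) {
    members <- which(P[i, ] == 1L)
    if (length(members) == 1L) {
      A[i, members] <- 1L
      next
    }
    repeat {
      chosen <- random_row(members)
      if (is.null(opp[[i]]) || row_respects_opposing(chosen, opp[[i]])) break
    }
    A[i, chosen] <- 1L
  }
  A
}

row_respects_opposing <- function(chosen, pairs) {
  !any(pairs[, 1L] %in% chosen & pairs[, 2L] %in% chosen)
}

#' Hamming distance between two allocations
#'
#' Total count of gene-pathway cells in which the two allocations disagree.
#'
#' @param a,b Allocation matrices of identical dimensions (or
#'   `allocation_fit` objects, whose allocation is used).
#' @return Non-negative integer.
#' @export
allocation_distance <- function(a, b) {
  a <- as_allocation_matrix(a)
  b <- as_allocation_matrix(b)
  if (!all(dim(a) == dim(b))) abort("allocations must have identical dimensions.")
  sum(abs(a - b))
}

# Accept an allocation_fit, synthetic planted matrix or a bare matrix.
as_allocation_matrix <- function(x) {
  if (inherits(x, "allocation_fit")) return(x$allocation)
  if (is.matrix(x)) return(x)
  abort("expected an allocation matrix or an `allocation_fit`.")
}
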