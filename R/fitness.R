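#' Per-pathway net expression of an allocation
#'
#' For pathway \eqn{j}, the net is the number of allocated up-regulated
#' genes minus the number of allocated down-regulated genes,
#' \eqn{\sum_i a_{ij} X(i)}. A strongly positive (negative) net marks a
#' pathway whose allocated genes agree on up- (down-) regulation.
#'
#' @inheritParams full_allocation
#' @param alloc Integer allocation matrix aligned to `membership`.
#' @return Named integer vector of length equal to the number of pathways.
#' @export
pathway_nets <- function(alloc, membership, states) {
  x <- state_vector(states, membership)
  if (!is.matrix(alloc) || !all(dim(alloc) == dim(membership$incidence))) {
    abort("`alloc` must be a matrix with the membership's dimensions.")
  }
  setNames(as.integer(colSums(alloc * as.numeric(x))), membership$pathways)
}

#' Consensus fitness of an allocation
#'
#' The objective maximised by all searches: the sum over pathways of the
#' absolute per-pathway net, \eqn{F(A) = \sum_j |\sum_i a_{ij} X(i)|}.
#' The more an allocation groups genes of like expression into the same
#' pathway — and separates contradicting genes into different member
#' pathways — the larger the fitness. The signed nets themselves are
#' available from [pathway_nets()].
#'
#' @inheritParams pathway_nets
#' @return A single non-negative number.
#' @export
total_fitness <- function(alloc, membership, states) {
  sum(abs(pathway_nets(alloc, membership, states)))
}

#' Per-pathway allocation summary
#'
#' Counts of up-, down-regulated and stable genes per pathway under a given
#' allocation, plus the signed and absolute nets — the numerical form of
#' the usual before/after pathway-state bar charts. Stable genes are never
#' allocated, so their counts come from the membership itself.
#'
#' @param fit An `allocation_fit` from [allocate_genes()], or an allocation
#'   matrix (then `membership` and `states` are required).
#' @inheritParams pathway_nets
#' @return A tibble with one row per pathway: `pathway`, `n_up`, `n_down`,
#'   `n_stable`, `net`, `abs_net`.
#' @export
pathway_summary <- function(fit, membership = NULL, states = NULL) {
  if (inherits(fit, "allocation_fit")) {
    membership <- fit$membership
    states <- fit$states
    alloc <- fit$allocation
  } else {
    alloc <- as_allocation_matrix(fit)
    if (is.null(membership) || is.null(states)) {
      abort("supply `membership` and `states` with a bare allocation matrix.")
    }
  }
  x <- state_vector(states, membership)
  up <- colSums(alloc[x == 1L, , drop = FALSE])
  down <- colSums(alloc[x == -1L, , drop = FALSE])
  stable <- colSums(membership$incidence[x == 0L, , drop = FALSE])
  net <- as.integer(up - down)
  tibble::tibble(
    pathway = membership$pathways,
    n_up = as.integer(up),
    n_down = as.integer(down),
    n_stable = as.integer(stable),
    net = net,
    abs_net = abs(net)
  )
}
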