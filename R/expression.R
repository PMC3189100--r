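#' Discretise log2 expression ratios into up/down/stable states
#'
#' A gene is called up-regulated (+1) when its log2 ratio exceeds the
#' threshold `c`, down-regulated (-1) below `-c`, and stable (0) otherwise.
#' Both inequalities are strict, so a ratio exactly at the threshold is
#' stable.
#'
#' @param values Numeric vector of finite log2 ratios.
#' @param threshold Positive threshold `c` in log2-ratio units.
#' @return Integer vector of the same length with values in `{-1, 0, 1}`.
#' @examples
#' discretize(c(5.849, -0.437, 1, -2.3), threshold = 1)
#' @export
discretize <- function(values, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0) {
    abort("`threshold` must be a single positive number.")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("expression values must all be finite numbers.")
  }
  out <- integer(length(values))
  out[values > threshold] <- 1L
  out[values < -threshold] <- -1L
  names(out) <- names(values)
  out
}

#' Per-gene expression states aligned to a membership
#'
#' Joins an expression table to the genes of a membership snapshot and
#' discretises the log2 ratios. Genes present in the expression table but
#' absent from the membership are dropped (with a message, mirroring the
#' usual trimming of array data to pathway-annotated genes); genes in the
#' membership with no measurement are treated as stable.
#'
#' @param expression Data frame whose first two columns are gene identifier
#'   and log2 ratio.
#' @param membership A [pathway_membership()] object, or `NULL` to keep the
#'   expression table's own gene universe.
#' @inheritParams discretize
#' @return A tibble with columns `gene`, `log2_ratio` (NA where unmeasured)
#'   and `state` (+1, -1 or 0), one row per membership gene when a
#'   membership is supplied.
#' @export
gene_states <- function(expression, membership = NULL, threshold = 1) {
  expression <- as.data.frame(expression)
  if (ncol(expression) < 2L) {
    abort("`expression` needs a gene column and a log2-ratio column.")
  }
  gene <- as.character(expression[[1L]])
  ratio <- expression[[2L]]
  if (!is.numeric(ratio)) abort("log2 ratios must be numeric.")
  if (anyDuplicated(gene)) {
    abort(sprintf("duplicate gene identifier(s): %s",
                  paste(unique(gene[duplicated(gene)]), collapse = ", ")))
  }
  if (is.null(membership)) {
    return(tibble::tibble(
      gene = gene,
      log2_ratio = as.numeric(ratio),
      state = discretize(as.numeric(ratio), threshold)
    ))
  }
  extra <- setdiff(gene, membership$genes)
  if (length(extra) > 0L) {
    inform(sprintf("dropping %d gene(s) absent from the membership.", length(extra)))
  }
  idx <- match(membership$genes, gene)
  if (anyNA(idx)) {
    inform(sprintf("%d membership gene(s) unmeasured; treated as stable.",
                   sum(is.na(idx))))
  }
  ratio_aligned <- as.numeric(ratio)[idx]
  state <- integer(length(idx))
  measured <- !is.na(idx)
  state[measured] <- discretize(ratio_aligned[measured], threshold)
  tibble::tibble(
    gene = membership$genes,
    log2_ratio = ratio_aligned,
    state = state
  )
}

# Internal: extract the aligned state vector (integer, named) from a
# gene_states tibble or a bare vector.
state_vector <- function(states, membership) {
  if (is.data.frame(states)) {
    if (!all(c("gene", "state") %in% names(states))) {
      abort("`states` data frame needs `gene` and `state` columns.")
    }
    v <- setNames(as.integer(states$state), states$gene)
  } else {
    v <- as.integer(states)
    names(v) <- names(states)
  }
  if (is.null(names(v))) {
    if (length(v) != length(membership$genes)) {
      abort("unnamed state vector must match the membership gene count.")
    }
    names(v) <- membership$genes
  }
  if (!all(membership$genes %in% names(v))) {
    abort("states are missing membership genes.")
  }
  v <- v[membership$genes]
  if (!all(v %in% c(-1L, 0L, 1L))) abort("states must be -1, 0 or +1.")
  v
}
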