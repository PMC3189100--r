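#' Build a gene-to-pathway membership object
#'
#' Converts a long table of (gene, pathway) pairs — as returned by
#' [read_gene_sets()] — into the binary incidence matrix \eqn{P} used by all
#' allocation searches. \eqn{p_{ij} = 1} iff gene \eqn{i} is annotated to
#' pathway (or module) \eqn{j}. The object is a snapshot: allocations may
#' drop genes from pathways but never add a membership absent from \eqn{P}.
#'
#' @param sets Data frame whose first two columns are gene identifier and
#'   pathway/module identifier (extra columns are ignored). Duplicate pairs
#'   collapse to a single membership with a warning. Gene and pathway order
#'   follow first appearance.
#'
#' @return An object of class `pathway_membership`: a list with elements
#'   `incidence` (integer genes-by-pathways matrix with dimnames), `genes`,
#'   `pathways` and `n_members` (per-gene membership counts).
#'
#' @examples
#' sets <- tibble::tribble(
#'   ~gene, ~pathway,
#'   "pgi", "glycolysis",
#'   "pgi", "ppp",
#'   "pfk", "glycolysis"
#' )
#' pathway_membership(sets)
#' @export
pathway_membership <- function(sets) {
  sets <- as.data.frame(sets)
  if (ncol(sets) < 2L || nrow(sets) == 0L) {
    abort("`sets` must be a non-empty data frame with gene and pathway columns.")
  }
  gene <- as.character(sets[[1L]])
  pathway <- as.character(sets[[2L]])
  if (anyNA(gene) || anyNA(pathway)) {
    abort("gene and pathway identifiers must not be missing.")
  }
  dup <- duplicated(paste(gene, pathway, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate gene-pathway pair(s).", sum(dup)))
    gene <- gene[!dup]
    pathway <- pathway[!dup]
  }
  genes <- unique(gene)
  pathways <- unique(pathway)
  P <- matrix(0L, length(genes), length(pathways),
              dimnames = list(genes, pathways))
  P[cbind(match(gene, genes), match(pathway, pathways))] <- 1L
  new_pathway_membership(P)
}

new_pathway_membership <- function(P) {
  stopifnot(is.matrix(P), all(P %in% c(0L, 1L)))
  if (any(rowSums(P) < 1L)) abort("every gene must belong to at least one pathway.")
  if (any(colSums(P) < 1L)) abort("every pathway must contain at least one gene.")
  structure(
    list(
      incidence = P,
      genes = rownames(P),
      pathways = colnames(P),
      n_members = rowSums(P)
    ),
    class = "pathway_membership"
  )
}

#' @export
print.pathway_membership <- function(x, ...) {
  multi <- sum(x$n_members > 1L)
  cat(sprintf(
    "<pathway_membership> %d genes x %d pathways (%d multi-membership genes)\n",
    length(x$genes), length(x$pathways), multi
  ))
  invisible(x)
}

#' @export
dim.pathway_membership <- function(x) dim(x$incidence)

#' Tidy a membership object back to a long table
#'
#' @param x A `pathway_membership`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `pathway` (one row per membership)
#'   and `n_members`, the gene's total membership count.
#' @exportS3Method generics::tidy
tidy.pathway_membership <- function(x, ...) {
  idx <- which(x$incidence == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(
    gene = x$genes[idx[, 1L]],
    pathway = x$pathways[idx[, 2L]],
    n_members = unname(x$n_members[idx[, 1L]])
  )
}

# Validate/normalise an opposing-pairs table against a membership.
# Returns a two-column character matrix (possibly 0-row).
check_opposing <- function(opposing, membership) {
  if (is.null(opposing)) {
    return(matrix(character(), 0L, 2L))
  }
  opposing <- as.data.frame(opposing)
  if (ncol(opposing) < 2L) abort("`opposing` needs two columns of module ids.")
  a <- as.character(opposing[[1L]])
  b <- as.character(opposing[[2L]])
  missing <- setdiff(c(a, b), membership$pathways)
  if (length(missing) > 0L) {
    abort(sprintf("opposing module(s) not in membership: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(a == b)) abort("a module cannot oppose itself.")
  # canonical unordered form, deduplicated
  pairs <- cbind(pmin(a, b), pmax(a, b))
  pairs[!duplicated(paste(pairs[, 1L], pairs[, 2L])), , drop = FALSE]
}

# Per-gene list of opposing member-pathway index pairs (list of 2-col
# integer matrices), NULL where the gene has no opposing constraint.
opposing_index <- function(membership, opposing_pairs) {
  P <- membership$incidence
  if (nrow(opposing_pairs) == 0L) return(vector("list", nrow(P)))
  ja <- match(opposing_pairs[, 1L], membership$pathways)
  jb <- match(opposing_pairs[, 2L], membership$pathways)
  lapply(seq_len(nrow(P)), function(i) {
    hit <- P[i, ja] == 1L & P[i, jb] == 1L
    if (!any(hit)) return(NULL)
    cbind(ja[hit], jb[hit])
  })
}
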