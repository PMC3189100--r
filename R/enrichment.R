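#' Hypergeometric pathway-enrichment p-value
#'
#' Probability of observing at least `overlap` affected genes in a pathway
#' (or cluster) of `set_size` genes, when `category_size` of the
#' `genome_size` genes on the platform are affected:
#' \deqn{p = 1 - \sum_{i=0}^{k-1}
#'   \binom{C}{i}\binom{G-C}{n-i} / \binom{G}{n},}
#' the upper tail of the hypergeometric distribution, evaluated through
#' [stats::phyper()] (which works in log space for large arguments).
#' Vectorised over its arguments.
#'
#' @param genome_size Total genes on the platform, `G`.
#' @param category_size Genes in the functional category, `C <= G`.
#' @param set_size Genes in the pathway or cluster, `n <= G`.
#' @param overlap Observed affected genes in the set, `k`, with
#'   `0 <= k <= min(C, n)`.
#' @return P-value(s) in `[0, 1]`; `overlap = 0` gives exactly 1.
#' @examples
#' enrichment_pvalue(10, 5, 4, 4)  # 5/210
#' @export
enrichment_pvalue <- function(genome_size, category_size, set_size, overlap) {
  n <- max(length(genome_size), length(category_size),
           length(set_size), length(overlap))
  G <- rep_len(genome_size, n)
  C <- rep_len(category_size, n)
  s <- rep_len(set_size, n)
  k <- rep_len(overlap, n)
  ints <- c(G, C, s, k)
  if (!is.numeric(ints) || any(!is.finite(ints)) || any(ints != round(ints))) {
    abort("all arguments must be finite integers.")
  }
  if (any(G < 1) || any(C < 0) || any(s < 0) || any(k < 0)) {
    abort("sizes must be non-negative (genome_size >= 1).")
  }
  if (any(C > G) || any(s > G)) {
    abort("category and set sizes cannot exceed the genome size.")
  }
  if (any(k > pmin(C, s))) {
    abort("`overlap` cannot exceed min(category_size, set_size).")
  }
  phyper(k - 1, C, G - C, s, lower.tail = FALSE)
}
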