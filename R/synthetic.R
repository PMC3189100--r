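#' Simulate a pathway-allocation instance with a planted solution
#'
#' Generates a desk-scale benchmark that emulates the net-effect premise of
#' multi-membership expression: each pathway has a latent activation
#' direction (+1 or -1); every gene is planted into a nonempty subset of
#' its member pathways; and its log2 ratio is the net effect of the planted
#' pathways' directions, plus half-normal noise on the log2 scale.
#' Expressed genes get magnitude `threshold + effect + |N(0, noise_sd)|`
#' with the sign of the net; genes whose planted directions cancel
#' (net 0) get a ratio drawn uniformly inside `(-threshold, threshold)` and
#' are therefore stable.
#'
#' Two planting schemes are available. `"coherent"` (default) samples one
#' direction per gene from the directions of its member pathways and plants
#' the gene in *all* member pathways of that direction; the planted
#' allocation is then the unique consensus-fitness optimum (given enough
#' single-membership genes anchoring each pathway), which is what a
#' parameter-recovery benchmark needs. `"random"` plants a uniform nonempty
#' subset of member pathways, so opposing contributions can cancel.
#'
#' @param n_genes,n_pathways Instance dimensions (`n_pathways >= 2`).
#' @param multi_fraction Fraction of genes with more than one membership.
#' @param max_memberships Maximum memberships per multi-membership gene.
#' @param threshold Discretisation threshold `c` (log2 units).
#' @param effect Expression margin above the threshold for expressed genes
#'   (log2 units); default `0.5 * threshold`.
#' @param noise_sd Standard deviation of the half-normal noise
#'   (default `0.25 * threshold`).
#' @param planting `"coherent"` or `"random"` (see Details).
#' @param seed Integer seed; the instance is reproducible from it.
#' @return A `synthetic_instance`: list with `membership`
#'   ([pathway_membership()]), `expression` (tibble `gene`, `log2_ratio`),
#'   `planted` (valid allocation matrix), `directions` (named +1/-1
#'   vector), `states` (tibble from [gene_states()]) and `params`.
#' @examples
#' inst <- simulate_instance(n_genes = 30, n_pathways = 6, seed = 7)
#' inst$directions
#' @export
simulate_instance <- function(n_genes = 60, n_pathways = 8,
                              multi_fraction = 0.4, max_memberships = 3,
                              threshold = 1, effect = 0.5 * threshold,
                              noise_sd = 0.25 * threshold,
                              planting = c("coherent", "random"),
                              seed = NULL) {
  planting <- match.arg(planting)
  if (multi_fraction < 0 || multi_fraction > 1) {
    abort("`multi_fraction` must be in [0, 1].")
  }
  if (n_pathways < 2 && multi_fraction > 0) {
    abort("multi-membership genes need at least 2 pathways.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (max_memberships < 2) abort("`max_memberships` must be >= 2.")
  max_memberships <- min(max_memberships, n_pathways)
  if (!is.null(seed)) set.seed(seed)

  M <- n_pathways
  N <- n_genes
  genes <- sprintf("g%03d", seq_len(N))
  pathways <- sprintf("pw%02d", seq_len(M))
  n_multi <- round(multi_fraction * N)
  is_multi <- seq_len(N) <= n_multi  # first block multi, rest single

  directions <- setNames(sample(c(-1L, 1L), M, replace = TRUE), pathways)

  # memberships; redraw single-gene homes until every pathway is covered
  member_sets <- vector("list", N)
  for (i in which(is_multi)) {
    n_i <- if (max_memberships == 2L) 2L else sample(2:max_memberships, 1L)
    member_sets[[i]] <- sort(sample.int(M, n_i))
  }
  singles <- which(!is_multi)
  for (attempt in seq_len(1000L)) {
    for (i in singles) member_sets[[i]] <- sample.int(M, 1L)
    covered <- sort(unique(unlist(member_sets)))
    if (length(covered) == M) break
    if (attempt == 1000L) abort("could not cover every pathway; add genes.")
  }
  P <- matrix(0L, N, M, dimnames = list(genes, pathways))
  for (i in seq_len(N)) P[i, member_sets[[i]]] <- 1L
  membership <- new_pathway_membership(P)

  planted <- matrix(0L, N, M, dimnames = list(genes, pathways))
  net <- integer(N)
  for (i in seq_len(N)) {
    mem <- member_sets[[i]]
    row <- if (!is_multi[i]) {
      mem
    } else if (planting == "coherent") {
      dirs <- directions[mem]
      mem[dirs == sample_one(unique(dirs))]
    } else {
      random_row(mem)
    }
    planted[i, row] <- 1L
    net[i] <- sum(directions[row])
  }

  s <- sign(net)
  magnitude <- threshold + effect + abs(rnorm(N, 0, noise_sd))
  log2_ratio <- ifelse(s != 0, s * magnitude, runif(N, -threshold, threshold))
  # stable genes take no part in the allocation problem
  planted[s == 0L, ] <- 0L

  expression <- tibble::tibble(gene = genes, log2_ratio = log2_ratio)
  states <- gene_states(expression, membership, threshold)
  structure(
    list(
      membership = membership,
      expression = expression,
      planted = planted,
      directions = directions,
      states = states,
      params = list(
        n_genes = N, n_pathways = M, multi_fraction = multi_fraction,
        max_memberships = max_memberships, threshold = threshold,
        effect = effect, noise_sd = noise_sd, planting = planting,
        seed = seed
      )
    ),
    class = "synthetic_instance"
  )
}

#' @export
print.synthetic_instance <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synthetic_instance> %d genes x %d pathways (%.0f%% multi, %s planting)\n",
    p$n_genes, p$n_pathways, 100 * p$multi_fraction, p$planting
  ))
  invisible(x)
}

#' How well does a found allocation recover the planted one?
#'
#' Compares a search result against the planted allocation of a synthetic
#' instance: Hamming similarity, fuzzy adjusted Rand index, the observed
#' Hamming distance with its lower-tail probability under the exact null
#' (small = closer than chance), and the consensus fitness of both
#' allocations.
#'
#' @param found An `allocation_fit` or allocation matrix.
#' @param instance A `synthetic_instance`.
#' @return A one-row tibble with columns `hamming_similarity`,
#'   `fuzzy_rand`, `distance`, `null_tail_p`, `fitness_found`,
#'   `fitness_planted`.
#' @export
recovery_report <- function(found, instance) {
  if (!inherits(instance, "synthetic_instance")) {
    abort("`instance` must be a `synthetic_instance`.")
  }
  A <- as_allocation_matrix(found)
  planted <- instance$planted
  if (!all(dim(A) == dim(planted))) {
    abort("`found` does not match the instance's dimensions.")
  }
  null <- allocation_null(instance$membership, instance$states)
  d <- allocation_distance(A, planted)
  d_capped <- min(d, max(null$distance))
  tibble::tibble(
    hamming_similarity = hamming_similarity(A, planted),
    fuzzy_rand = as.numeric(fuzzy_rand_index(A, planted)),
    distance = d,
    null_tail_p = null_tail_probability(null, d_capped),
    fitness_found = total_fitness(A, instance$membership, instance$states),
    fitness_planted = total_fitness(planted, instance$membership,
                                    instance$states)
  )
}
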