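# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive: exhaustive enumeration and hand-rolled arithmetic,
# kept separate from the package's own code paths.

# all valid 0/1 rows (as integer vectors over `members`) for a gene,
# optionally excluding rows occupying both sides of an opposing pair
# (pairs given as a 2-column matrix of pathway names)
oracle_valid_rows <- function(members, opposing_names = NULL) {
  n <- length(members)
  rows <- list()
  for (k in seq_len(2^n - 1)) {
    bits <- as.integer(intToBits(k)[seq_len(n)])
    chosen <- members[bits == 1L]
    if (!is.null(opposing_names) && nrow(opposing_names) > 0L) {
      bad <- any(opposing_names[, 1L] %in% chosen &
                   opposing_names[, 2L] %in% chosen)
      if (bad) next
    }
    rows[[length(rows) + 1L]] <- bits
  }
  rows
}

# naive fitness: per-pathway sum of allocated states, absolute, summed
oracle_fitness <- function(A, x) {
  x <- unname(x)
  f <- 0
  for (j in seq_len(ncol(A))) {
    net <- 0
    for (i in seq_len(nrow(A))) net <- net + A[i, j] * x[i]
    f <- f + abs(net)
  }
  f
}

# exhaustive maximum fitness over all valid allocations (free genes only;
# instances must stay small: product of per-gene row counts <= ~5000)
oracle_max_fitness <- function(membership, states, opposing = NULL) {
  P <- membership$incidence
  if (is.data.frame(states)) {
    x <- stats::setNames(states$state, states$gene)[membership$genes]
  } else {
    x <- states[membership$genes]
  }
  opp <- if (is.null(opposing)) NULL else as.matrix(as.data.frame(opposing))
  expressed <- x != 0L
  free <- which(expressed & rowSums(P) > 1L)
  A0 <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  fixed <- expressed & rowSums(P) == 1L
  A0[fixed, ] <- P[fixed, , drop = FALSE]
  if (length(free) == 0L) return(oracle_fitness(A0, x))
  options_per_gene <- lapply(free, function(i) {
    members <- colnames(P)[P[i, ] == 1L]
    oracle_valid_rows(members, opp)
  })
  members_per_gene <- lapply(free, function(i) which(P[i, ] == 1L))
  grid <- do.call(expand.grid, lapply(options_per_gene, seq_along))
  best <- -Inf
  for (g in seq_len(nrow(grid))) {
    A <- A0
    for (k in seq_along(free)) {
      A[free[k], members_per_gene[[k]]] <- options_per_gene[[k]][[grid[g, k]]]
    }
    best <- max(best, oracle_fitness(A, x))
  }
  best
}

# exhaustive ordered-pair Hamming distance counts for one gene with n
# member pathways
oracle_pair_counts <- function(n) {
  strings <- oracle_valid_rows(seq_len(n))
  counts <- numeric(n + 1L)
  for (a in strings) {
    for (b in strings) {
      d <- sum(a != b)
      counts[d + 1L] <- counts[d + 1L] + 1
    }
  }
  counts
}

# direct log-space evaluation of the hypergeometric upper tail
oracle_enrichment <- function(G, C, n, k) {
  if (k == 0) return(1)
  i <- 0:(k - 1)
  terms <- lchoose(C, i) + lchoose(G - C, n - i) - lchoose(G, n)
  1 - sum(exp(terms))
}

# small random instance whose free allocation bits number <= 12
make_oracle_instance <- function(seed) {
  set.seed(seed)
  M <- sample(3:4, 1L)
  pathways <- paste0("P", seq_len(M))
  repeat {
    n_free <- sample(2:4, 1L)
    sizes <- sample(2:min(3L, M), n_free, replace = TRUE)
    if (sum(sizes) <= 12L) break
  }
  n_single <- sample(3:5, 1L)
  rows <- list()
  for (g in seq_len(n_free)) {
    mem <- sample(pathways, sizes[g])
    rows[[g]] <- data.frame(gene = paste0("f", g), pathway = mem)
  }
  # singles cover every pathway so no column is empty
  homes <- c(pathways, sample(pathways, max(0L, n_single - M), replace = TRUE))
  homes <- homes[seq_len(max(n_single, M))]
  for (s in seq_along(homes)) {
    rows[[n_free + s]] <- data.frame(gene = paste0("s", s), pathway = homes[s])
  }
  sets <- do.call(rbind, rows)
  membership <- pathway_membership(sets)
  genes <- membership$genes
  ratio <- sample(c(-2, 2), length(genes), replace = TRUE)
  expression <- data.frame(gene = genes, log2_ratio = ratio)
  list(membership = membership, expression = expression,
       states = gene_states(expression, membership, threshold = 1))
}

# crafted landscape with a strict local maximum below the global optimum:
# pathway A is shared by 2 up-regulated genes (also in B) and 3
# down-regulated genes (also in C); anchors fix B up and C down. The
# all-up reading of A (f = 9) is locally stable but the down-dominated
# reading (f = 10) is the optimum.
make_trap_instance <- function() {
  sets <- rbind(
    data.frame(gene = "anchor_b", pathway = "B"),
    data.frame(gene = "anchor_c", pathway = "C"),
    data.frame(gene = c("u1", "u1", "u2", "u2"),
               pathway = c("A", "B", "A", "B")),
    data.frame(gene = c("d1", "d1", "d2", "d2", "d3", "d3"),
               pathway = c("A", "C", "A", "C", "A", "C"))
  )
  membership <- pathway_membership(sets)
  expression <- data.frame(
    gene = c("anchor_b", "anchor_c", "u1", "u2", "d1", "d2", "d3"),
    log2_ratio = c(2, -2, 2, 2, -2, -2, -2)
  )
  list(membership = membership, expression = expression,
       states = gene_states(expression, membership, threshold = 1))
}

# opposing-module fixture: glycolysis/gluconeogenesis-style pair sharing
# four expressed genes, plus a third unconstrained module
make_module_instance <- function() {
  sets <- read_gene_sets(
    pathalloc_example("glyco_modules_synthetic.gmt"), format = "gmt"
  )
  membership <- pathway_membership(sets)
  genes <- membership$genes
  set.seed(99)
  expression <- data.frame(
    gene = genes,
    log2_ratio = ifelse(genes %in% c("fbp1", "pck1"), 2.5,
                        sample(c(-2.2, 1.8), length(genes), replace = TRUE))
  )
  opposing <- data.frame(module_a = "m_glycolysis",
                         module_b = "m_gluconeogenesis")
  list(membership = membership, expression = expression, opposing = opposing)
}
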