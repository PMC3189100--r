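#' Probability of accepting a worsening move (simulated annealing)
#'
#' Implements the Boltzmann acceptance rule: a move that lowers the fitness
#' by `delta_fitness` is accepted with probability
#' \eqn{e^{-\Delta F / T}}; moves that keep or improve the fitness are
#' always accepted.
#'
#' @param delta_fitness Fitness decrease \eqn{\Delta F} of the proposed
#'   move (0 or negative values mean no loss). May be a vector.
#' @param temperature Current temperature, strictly positive.
#' @return Probability (vector) in `(0, 1]`.
#' @examples
#' acceptance_probability(0, 1)    # 1
#' acceptance_probability(1, 1)    # exp(-1)
#' @export
acceptance_probability <- function(delta_fitness, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    abort("`temperature` must be positive.")
  }
  ifelse(delta_fitness <= 0, 1, exp(-delta_fitness / temperature))
}

#' Geometric cooling schedule
#'
#' Temperature at iteration `t` of a geometric schedule
#' \eqn{T_t = T_0 \lambda^t} with
#' \eqn{\lambda = e^{(\log T_{final} - \log T_0)/I}}, so that \eqn{T_0} is
#' the starting temperature and \eqn{T_I = T_{final}} exactly. The default
#' constants (1 down to 0.01 over 10000 iterations) give
#' \eqn{\lambda \approx 0.99954}.
#'
#' @param t Iteration index (vectorised), between 0 and `iterations`.
#' @param iterations Total number of iterations `I`.
#' @param t0,t_final Initial and final temperatures, `0 < t_final < t0`.
#' @return Temperature(s) at `t`.
#' @export
temperature_schedule <- function(t, iterations = 10000, t0 = 1, t_final = 0.01) {
  if (!(t_final > 0 && t_final < t0)) abort("need 0 < t_final < t0.")
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (any(t < 0 | t > iterations)) abort("`t` must lie in [0, iterations].")
  lambda <- exp((log(t_final) - log(t0)) / iterations)
  t0 * lambda^t
}

# ---------------------------------------------------------------------------
# Internal search context: everything precomputed once per search.

search_context <- function(membership, states, opposing = NULL) {
  P <- membership$incidence
  x <- state_vector(states, membership)
  pairs <- check_opposing(opposing, membership)
  opp <- opposing_index(membership, pairs)
  expressed <- x != 0L
  free <- expressed & membership$n_members > 1L
  free_idx <- which(free)
  members <- lapply(free_idx, function(i) which(P[i, ] == 1L))
  # rows that never move: expressed single-membership genes
  A_fixed <- matrix(0L, nrow(P), ncol(P), dimnames = dimnames(P))
  single <- expressed & membership$n_members == 1L
  A_fixed[single, ] <- P[single, , drop = FALSE]
  list(
    P = P, x = x, membership = membership,
    opp = opp, pairs = pairs,
    free_idx = free_idx, members = members,
    n_free = length(free_idx),
    A_fixed = A_fixed,
    fixed_nets = as.numeric(colSums(A_fixed * as.numeric(x)))
  )
}

# Apply the opposing-pair repair to a row after `added` was set to 1:
# the gene leaves the paired module. `mem` are the row's member columns,
# `r` the 0/1 values over `mem`.
repair_opposing_row <- function(r, mem, added, gene_pairs) {
  if (is.null(gene_pairs)) return(r)
  for (k in seq_len(nrow(gene_pairs))) {
    ja <- gene_pairs[k, 1L]
    jb <- gene_pairs[k, 2L]
    if (added == ja) r[mem == jb] <- 0L
    if (added == jb) r[mem == ja] <- 0L
  }
  r
}

# Random valid row for free gene slot `g` of the context.
random_free_row <- function(ctx, g) {
  mem <- ctx$members[[g]]
  i <- ctx$free_idx[g]
  repeat {
    chosen <- random_row(mem)
    if (is.null(ctx$opp[[i]]) || row_respects_opposing(chosen, ctx$opp[[i]])) break
  }
  as.integer(mem %in% chosen)
}

# One move proposal on the row of free-gene slot g: toggle a uniformly
# chosen member bit; reassign if the row empties; repair opposing pairs on
# adds. Returns the new 0/1 values over the member columns.
propose_row <- function(ctx, g, r) {
  mem <- ctx$members[[g]]
  i <- ctx$free_idx[g]
  pos <- sample.int(length(mem), 1L)
  added <- NA_integer_
  if (r[pos] == 1L) {
    r[pos] <- 0L
    if (sum(r) == 0L) {
      # forced reassignment: the gene must stay in at least one pathway
      pos2 <- sample.int(length(mem), 1L)
      r[pos2] <- 1L
      added <- mem[pos2]
    }
  } else {
    r[pos] <- 1L
    added <- mem[pos]
  }
  if (!is.na(added)) r <- repair_opposing_row(r, mem, added, ctx$opp[[i]])
  r
}

#' Propose a single allocation move
#'
#' The elementary move used by hill climbing and simulated annealing: pick
#' an expressed multi-membership gene uniformly at random, pick one of its
#' member pathways uniformly, and toggle its allocation bit. If the removal
#' would leave the gene allocated nowhere, it is reassigned to a uniformly
#' chosen member pathway. In module mode, allocating a gene to one member
#' of an opposing pair removes it from the other.
#'
#' @inheritParams is_valid_allocation
#' @param seed Optional integer seed.
#' @return A list with `allocation` (the resulting valid matrix) and
#'   `move`, a one-row tibble (`gene`, `pathway`, `action`).
#' @export
propose_move <- function(alloc, membership, states, opposing = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- search_context(membership, states, opposing)
  if (ctx$n_free == 0L) {
    abort("nothing to optimize: no expressed multi-membership gene.",
          class = "pathalloc_nothing_to_optimize")
  }
  g <- sample.int(ctx$n_free, 1L)
  i <- ctx$free_idx[g]
  mem <- ctx$members[[g]]
  r_old <- alloc[i, mem]
  r_new <- propose_row(ctx, g, r_old)
  alloc[i, mem] <- r_new
  removed <- mem[r_old == 1L & r_new == 0L]
  added <- mem[r_old == 0L & r_new == 1L]
  action <- if (length(added) > 0L && length(removed) > 0L) {
    "toggle+reassign"
  } else if (length(added) > 0L) "add" else "remove"
  list(
    allocation = alloc,
    move = tibble::tibble(
      gene = ctx$membership$genes[i],
      pathway = paste(ctx$membership$pathways[c(removed, added)], collapse = ","),
      action = action
    )
  )
}

# ---------------------------------------------------------------------------
# Hill climbing / simulated annealing engine. `hill = TRUE` sets the
# worsening-acceptance probability to zero; the acceptance uniform is drawn
# for every worsening proposal in both methods, so simulated annealing at
# vanishing temperature is bit-identical to hill climbing on the same seed.

run_local_search <- function(ctx, iterations, t0, t_final, hill) {
  A <- ctx$A_fixed
  for (g in seq_len(ctx$n_free)) {
    A[ctx$free_idx[g], ctx$members[[g]]] <- random_free_row(ctx, g)
  }
  nets <- as.numeric(colSums(A * as.numeric(ctx$x)))
  f <- sum(abs(nets))
  best_A <- A
  best_f <- f
  conv <- 0L
  trace <- numeric(iterations)
  if (ctx$n_free == 0L) {
    trace[] <- f
    return(list(allocation = A, fitness = f, trace = trace, convergence = 0L))
  }
  lambda <- exp((log(t_final) - log(t0)) / iterations)
  temp <- t0
  xi <- as.numeric(ctx$x)
  for (t in seq_len(iterations)) {
    temp <- temp * lambda
    g <- sample.int(ctx$n_free, 1L)
    i <- ctx$free_idx[g]
    mem <- ctx$members[[g]]
    r_old <- A[i, mem]
    r_new <- propose_row(ctx, g, r_old)
    dn <- (r_new - r_old) * xi[i]
    delta <- sum(abs(nets[mem] + dn)) - sum(abs(nets[mem]))
    accept <- TRUE
    if (delta < 0) {
      u <- runif(1L)
      p <- if (hill) 0 else exp(delta / temp)
      accept <- u < p
    }
    if (accept) {
      A[i, mem] <- r_new
      nets[mem] <- nets[mem] + dn
      f <- f + delta
      if (f > best_f) {
        best_f <- f
        best_A <- A
        conv <- t
      }
    }
    trace[t] <- best_f
  }
  list(allocation = best_A, fitness = best_f, trace = trace, convergence = conv)
}

# ---------------------------------------------------------------------------
# Genetic algorithm engine. Individuals are the free-gene rows only; the
# fixed part of the allocation contributes a constant net vector.

run_ga <- function(ctx, pop_size, generations) {
  if (pop_size < 2L) abort("`pop_size` must be at least 2.")
  n_free <- ctx$n_free
  if (n_free == 0L) {
    f <- sum(abs(ctx$fixed_nets))
    return(list(allocation = ctx$A_fixed, fitness = f,
                trace = rep(f, generations), convergence = 0L))
  }
  M <- ncol(ctx$P)
  x_free <- as.numeric(ctx$x[ctx$free_idx])
  # individuals: n_free x length(members) ragged rows -> store as
  # n_free x M_k lists? use per-gene member-column matrices of width
  # max members; simplest: n_free x max_width with per-gene member map.
  widths <- lengths(ctx$members)
  new_individual <- function() {
    ind <- matrix(0L, n_free, max(widths, 1L))
    for (g in seq_len(n_free)) {
      ind[g, seq_len(widths[g])] <- random_free_row(ctx, g)
    }
    ind
  }
  ind_nets <- function(ind) {
    nets <- ctx$fixed_nets
    for (g in seq_len(n_free)) {
      nets[ctx$members[[g]]] <- nets[ctx$members[[g]]] +
        ind[g, seq_len(widths[g])] * x_free[g]
    }
    nets
  }
  fitness_of <- function(ind) sum(abs(ind_nets(ind)))
  mutate_ind <- function(ind) {
    rate <- 1 / n_free
    for (g in seq_len(n_free)) {
      if (runif(1L) >= rate) next
      mem <- ctx$members[[g]]
      i <- ctx$free_idx[g]
      r <- ind[g, seq_len(widths[g])]
      repeat {
        pos <- sample.int(length(mem), 1L)
        if (!(r[pos] == 1L && sum(r) == 1L)) break
      }
      r[pos] <- 1L - r[pos]
      if (r[pos] == 1L) r <- repair_opposing_row(r, mem, mem[pos], ctx$opp[[i]])
      ind[g, seq_len(widths[g])] <- r
    }
    ind
  }
  pop <- replicate(pop_size, new_individual(), simplify = FALSE)
  fit <- vapply(pop, fitness_of, numeric(1L))
  trace <- numeric(generations)
  conv <- 0L
  best_prev <- max(fit)
  for (gen in seq_len(generations)) {
    mutated <- lapply(pop, mutate_ind)
    perm <- sample.int(pop_size)
    offspring <- vector("list", pop_size)
    n_off <- 0L
    k <- 1L
    while (k + 1L <= pop_size) {
      pa <- mutated[[perm[k]]]
      pb <- mutated[[perm[k + 1L]]]
      cut <- sample.int(n_free, 1L)
      ca <- pa; cb <- pb
      if (cut < n_free) {
        tail_rows <- (cut + 1L):n_free
        ca[tail_rows, ] <- pb[tail_rows, , drop = FALSE]
        cb[tail_rows, ] <- pa[tail_rows, , drop = FALSE]
      }
      offspring[[n_off + 1L]] <- ca
      offspring[[n_off + 2L]] <- cb
      n_off <- n_off + 2L
      k <- k + 2L
    }
    if (k == pop_size) {
      # odd leftover passes through unchanged
      offspring[[n_off + 1L]] <- mutated[[perm[k]]]
      n_off <- n_off + 1L
    }
    offspring <- offspring[seq_len(n_off)]
    pool <- c(pop, mutated, offspring)
    pf <- c(fit,
            vapply(mutated, fitness_of, numeric(1L)),
            vapply(offspring, fitness_of, numeric(1L)))
    keep <- order(pf, decreasing = TRUE)[seq_len(pop_size)]
    pop <- pool[keep]
    fit <- pf[keep]
    trace[gen] <- fit[1L]
    if (fit[1L] > best_prev) {
      best_prev <- fit[1L]
      conv <- gen
    }
  }
  # expand the best individual to a full allocation matrix
  best <- pop[[1L]]
  A <- ctx$A_fixed
  for (g in seq_len(n_free)) {
    A[ctx$free_idx[g], ctx$members[[g]]] <- best[g, seq_len(widths[g])]
  }
  list(allocation = A, fitness = fit[1L], trace = trace, convergence = conv)
}

# ---------------------------------------------------------------------------

#' Genetic-algorithm mutation of an allocation
#'
#' For each expressed multi-membership gene, with probability 1 over the
#' number of such genes, one uniformly chosen member-pathway bit is
#' flipped. A flip that would leave the gene allocated nowhere is redrawn,
#' so the result is always valid; in module mode, an add triggers the
#' opposing-pair repair. An allocation with no expressed multi-membership
#' gene is returned unchanged.
#'
#' @inheritParams is_valid_allocation
#' @param seed Optional integer seed.
#' @return A valid allocation matrix.
#' @export
mutate_allocation <- function(alloc, membership, states, opposing = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- search_context(membership, states, opposing)
  if (ctx$n_free == 0L) return(alloc)
  rate <- 1 / ctx$n_free
  for (g in seq_len(ctx$n_free)) {
    if (runif(1L) >= rate) next
    mem <- ctx$members[[g]]
    i <- ctx$free_idx[g]
    r <- alloc[i, mem]
    repeat {
      pos <- sample.int(length(mem), 1L)
      if (!(r[pos] == 1L && sum(r) == 1L)) break
    }
    r[pos] <- 1L - r[pos]
    if (r[pos] == 1L) r <- repair_opposing_row(r, mem, mem[pos], ctx$opp[[i]])
    alloc[i, mem] <- r
  }
  alloc
}

#' Single-point crossover of two allocations
#'
#' Chooses a cut point `x` uniformly on the gene list; the first child
#' takes gene rows `1..x` from the first parent and the rest from the
#' second, the second child the complement. Rows are inherited whole, so
#' both children are valid whenever the parents are.
#'
#' @param a,b Valid allocation matrices over the same membership.
#' @param seed Optional integer seed.
#' @return A list of two allocation matrices, `child_a` and `child_b`.
#' @export
crossover_allocation <- function(a, b, seed = NULL) {
  a <- as_allocation_matrix(a)
  b <- as_allocation_matrix(b)
  if (!all(dim(a) == dim(b))) abort("parents must have identical dimensions.")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  cut <- sample.int(n, 1L)
  ca <- a
  cb <- b
  if (cut < n) {
    tail_rows <- (cut + 1L):n
    ca[tail_rows, ] <- b[tail_rows, , drop = FALSE]
    cb[tail_rows, ] <- a[tail_rows, , drop = FALSE]
  }
  list(child_a = ca, child_b = cb)
}

#' Search for a high-consensus gene-to-pathway allocation
#'
#' Discretises the expression table at `threshold`, builds the space of
#' valid allocations (every expressed gene kept in at least one of its
#' member pathways, single-membership genes fixed, stable genes excluded)
#' and maximises the consensus fitness [total_fitness()] with one of three
#' metaheuristics:
#'
#' * `"hc"` — hill climbing: random single-bit moves, accepted unless they
#'   strictly decrease the fitness (plateau moves are accepted);
#' * `"sa"` — simulated annealing: as hill climbing, but a worsening move
#'   is accepted with probability [acceptance_probability()] under the
#'   geometric [temperature_schedule()]; the best allocation seen is
#'   returned;
#' * `"ga"` — genetic algorithm: a population of valid allocations evolves
#'   by per-gene mutation (rate 1/number of free genes), single-point
#'   crossover on the gene list, and elitist truncation selection.
#'
#' In module mode an `opposing` table of mutually exclusive module pairs
#' (e.g. glycolysis vs gluconeogenesis) may be given: a shared gene is
#' never allocated to both members of a pair, and allocating it to one side
#' removes it from the other.
#'
#' @inheritParams gene_states
#' @param membership A [pathway_membership()].
#' @param expression Data frame: gene identifier, log2 ratio.
#' @param method `"sa"`, `"hc"` or `"ga"`.
#' @param mode `"pathway"` or `"module"`; defaults to `"module"` when
#'   `opposing` is supplied.
#' @param opposing Optional two-column data frame of opposing module pairs.
#' @param iterations Move proposals for `"hc"`/`"sa"` (default 10000).
#' @param t0,t_final Simulated-annealing temperature bounds (1 and 0.01).
#' @param pop_size,generations Genetic-algorithm population size (100) and
#'   number of generations (400).
#' @param seed Integer seed; if omitted, a recorded default (2011) is used
#'   and reported, so every run is reproducible.
#' @return An `allocation_fit` object: list with `allocation` (matrix),
#'   `fitness`, `nets`, `trace`, `convergence`, `method`, `mode`, `seed`,
#'   `membership`, `states` and `config`. Methods: [tidy()], [glance()],
#'   [autoplot()], [pathway_summary()].
#' @examples
#' inst <- simulate_instance(n_genes = 20, n_pathways = 4, seed = 1)
#' fit <- allocate_genes(inst$membership, inst$expression,
#'                       method = "sa", iterations = 500, seed = 1)
#' glance(fit)
#' @export
allocate_genes <- function(membership, expression, threshold = 1,
                           method = c("sa", "hc", "ga"),
                           mode = c("pathway", "module"),
                           opposing = NULL,
                           iterations = 10000, t0 = 1, t_final = 0.01,
                           pop_size = 100, generations = 400,
                           seed = NULL) {
  method <- match.arg(method)
  if (missing(mode) && !is.null(opposing)) {
    mode <- "module"
  } else {
    mode <- match.arg(mode)
  }
  if (mode == "pathway") opposing <- NULL
  if (!(t_final > 0 && t_final < t0)) abort("need 0 < t_final < t0.")
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (is.null(seed)) {
    seed <- 2011L
    inform("no seed given; using recorded default seed 2011.")
  }
  set.seed(seed)
  states <- gene_states(expression, membership, threshold)
  ctx <- search_context(membership, states, opposing)
  if (ctx$n_free == 0L) {
    inform("nothing to optimize: no expressed multi-membership gene.")
  }
  res <- switch(method,
    hc = run_local_search(ctx, iterations, t0, t_final, hill = TRUE),
    sa = run_local_search(ctx, iterations, t0, t_final, hill = FALSE),
    ga = run_ga(ctx, pop_size, generations)
  )
  evals_per_step <- if (method == "ga") {
    pop_size + 2L * (pop_size %/% 2L) + pop_size %% 2L
  } else {
    1L
  }
  structure(
    list(
      allocation = res$allocation,
      fitness = res$fitness,
      nets = pathway_nets(res$allocation, membership, states),
      trace = res$trace,
      convergence = res$convergence,
      fitness_evals_per_step = evals_per_step,
      method = method,
      mode = mode,
      opposing = if (is.null(opposing)) NULL else as.data.frame(opposing),
      seed = seed,
      membership = membership,
      states = states,
      config = list(
        method = method, mode = mode, threshold = threshold,
        iterations = iterations, t0 = t0, t_final = t_final,
        pop_size = pop_size, generations = generations, seed = seed
      )
    ),
    class = "allocation_fit"
  )
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat(sprintf(
    "<allocation_fit> method=%s mode=%s fitness=%g (seed %d)\n",
    x$method, x$mode, x$fitness, x$seed
  ))
  cat(sprintf("  %d genes x %d pathways; converged at step %d of %d\n",
              nrow(x$allocation), ncol(x$allocation), x$convergence,
              length(x$trace)))
  invisible(x)
}
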