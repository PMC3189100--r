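#' Tidy an allocation fit into a long table
#'
#' @param x An `allocation_fit` from [allocate_genes()].
#' @param ... Unused.
#' @return A tibble with one row per gene-pathway membership: `gene`,
#'   `pathway`, `allocated` (0/1 under the fitted allocation) and `state`
#'   (+1/-1/0).
#' @exportS3Method generics::tidy
tidy.allocation_fit <- function(x, ...) {
  long <- tidy(x$membership)
  idx <- cbind(match(long$gene, x$membership$genes),
               match(long$pathway, x$membership$pathways))
  states <- state_vector(x$states, x$membership)
  tibble::tibble(
    gene = long$gene,
    pathway = long$pathway,
    allocated = as.integer(x$allocation[idx]),
    state = unname(states[long$gene])
  )
}

#' One-row summary of an allocation fit
#'
#' @inheritParams tidy.allocation_fit
#' @return A tibble with the method, mode, final consensus fitness, the
#'   fitness of the full-membership allocation it improved on, counts of
#'   genes by role, convergence step and seed.
#' @exportS3Method generics::glance
glance.allocation_fit <- function(x, ...) {
  states <- state_vector(x$states, x$membership)
  expressed <- states != 0L
  full <- full_allocation(x$membership, x$states)
  tibble::tibble(
    method = x$method,
    mode = x$mode,
    fitness = x$fitness,
    full_membership_fitness = total_fitness(full, x$membership, x$states),
    n_genes = length(states),
    n_expressed = sum(expressed),
    n_free = sum(expressed & x$membership$n_members > 1L),
    steps = length(x$trace),
    convergence = x$convergence,
    seed = x$seed
  )
}

#' Fitness trace of a search as a tibble
#'
#' @param fit An `allocation_fit`.
#' @return A tibble with `step` (iteration or generation), `best_fitness`,
#'   and `fitness_evals`, the cumulative number of fitness evaluations —
#'   comparable across the single-solution searches and the
#'   population-based genetic algorithm.
#' @export
fitness_trace <- function(fit) {
  stopifnot(inherits(fit, "allocation_fit"))
  tibble::tibble(
    step = seq_along(fit$trace),
    best_fitness = fit$trace,
    fitness_evals = seq_along(fit$trace) * fit$fitness_evals_per_step
  )
}

#' Plot the convergence of an allocation search
#'
#' @param object An `allocation_fit`.
#' @param ... Unused.
#' @return A ggplot: best-so-far consensus fitness against search step.
#' @exportS3Method ggplot2::autoplot
autoplot.allocation_fit <- function(object, ...) {
  df <- fitness_trace(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = if (object$method == "ga") "generation" else "iteration",
      y = "best consensus fitness",
      title = sprintf("%s search (seed %d)", toupper(object$method),
                      object$seed)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.allocation_fit <- function(x, ...) print(autoplot(x, ...))

#' Tidy a Hamming null distribution
#'
#' @param x A `hamming_null`.
#' @param ... Unused.
#' @return The underlying tibble (`distance`, `count`, `probability`).
#' @exportS3Method generics::tidy
tidy.hamming_null <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Moments and size of a Hamming null distribution
#'
#' @inheritParams tidy.hamming_null
#' @return A one-row tibble: number of genes combined, maximum distance,
#'   total ordered pairs, and the exact mean and standard deviation of the
#'   null distance — the yardstick for judging observed distances.
#' @exportS3Method generics::glance
glance.hamming_null <- function(x, ...) {
  mu <- sum(x$distance * x$probability)
  sigma2 <- sum((x$distance - mu)^2 * x$probability)
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    max_distance = max(x$distance),
    total_pairs = attr(x, "total_pairs"),
    mean = mu,
    sd = sqrt(sigma2)
  )
}

#' Plot an exact Hamming null distribution
#'
#' @param object A `hamming_null`.
#' @param ... Unused.
#' @return A ggplot bar chart of the probability mass function.
#' @exportS3Method ggplot2::autoplot
autoplot.hamming_null <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$distance, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Hamming distance", y = "probability",
                  title = sprintf("Exact null over %d gene(s)",
                                  attr(object, "n_genes"))) +
    ggplot2::theme_minimal()
}
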