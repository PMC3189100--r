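test_that("the Boltzmann acceptance rule matches its closed form", {
  expect_equal(acceptance_probability(0, 1), 1)
  expect_equal(acceptance_probability(-3, 0.5), 1)  # improving move
  expect_equal(acceptance_probability(1, 1), exp(-1))
  expect_equal(acceptance_probability(2, 0.01), exp(-200))
  expect_error(acceptance_probability(1, 0), "positive")
  expect_error(acceptance_probability(1, -2), "positive")
})

test_that("the geometric schedule hits both temperature endpoints", {
  expect_equal(temperature_schedule(0), 1)
  expect_equal(temperature_schedule(10000), 0.01, tolerance = 1e-12)
  lambda <- temperature_schedule(1) / temperature_schedule(0)
  expect_equal(lambda, exp(log(0.01) / 10000), tolerance = 1e-12)
  expect_equal(temperature_schedule(500, 1000, 2, 0.5),
               2 * exp(log(0.25) / 1000 * 500))
  expect_error(temperature_schedule(1, 100, 1, 2), "t_final")
  expect_error(temperature_schedule(-1), "\\[0, iterations\\]")
})

test_that("proposed moves keep allocations valid and respect reassignment", {
  for (seed in 1:15) {
    inst <- make_oracle_instance(seed)
    A <- random_allocation(inst$membership, inst$states, seed = seed)
    out <- propose_move(A, inst$membership, inst$states, seed = seed + 1)
    expect_true(is_valid_allocation(out$allocation, inst$membership,
                                    inst$states))
    # exactly one gene's row changed
    changed <- which(rowSums(abs(out$allocation - A)) > 0)
    expect_lte(length(changed), 1L)
  }
  # no expressed multi-membership gene -> nothing to optimise
  mem <- pathway_membership(data.frame(gene = c("a", "b"),
                                       pathway = c("P", "Q")))
  st <- gene_states(data.frame(gene = c("a", "b"), log2_ratio = c(2, -2)), mem)
  A <- full_allocation(mem, st)
  expect_error(propose_move(A, mem, st),
               class = "pathalloc_nothing_to_optimize")
})

test_that("hill climbing has a monotone trace and solves the two-gene instance", {
  p_sets <- data.frame(gene = c("up", "up", "down", "down"),
                       pathway = c("A", "B", "A", "B"))
  mem <- pathway_membership(p_sets)
  expr <- data.frame(gene = c("up", "down"), log2_ratio = c(2, -2))
  for (seed in 1:10) {
    fit <- allocate_genes(mem, expr, method = "hc", iterations = 300,
                          seed = seed)
    expect_true(all(diff(fit$trace) >= 0))
    expect_equal(fit$fitness, 2)
    expect_equal(fit$fitness, total_fitness(fit$allocation, mem, fit$states))
  }
})

test_that("searches leave single-membership-only instances untouched", {
  mem <- pathway_membership(data.frame(gene = c("a", "b", "c"),
                                       pathway = c("P", "Q", "P")))
  expr <- data.frame(gene = c("a", "b", "c"), log2_ratio = c(2, -2, 3))
  for (m in c("hc", "sa", "ga")) {
    expect_message(
      fit <- allocate_genes(mem, expr, method = m, iterations = 50,
                            pop_size = 10, generations = 5, seed = 1),
      "nothing to optimize"
    )
    st <- gene_states(expr, mem)
    expect_identical(fit$allocation, full_allocation(mem, st))
    expect_true(all(fit$trace == fit$fitness))
  }
})

test_that("simulated annealing at vanishing temperature equals hill climbing", {
  inst <- make_oracle_instance(3)
  hc <- allocate_genes(inst$membership, inst$expression, method = "hc",
                       iterations = 400, seed = 17)
  sa <- allocate_genes(inst$membership, inst$expression, method = "sa",
                       iterations = 400, t0 = 1e-9, t_final = 1e-10,
                       seed = 17)
  expect_identical(sa$allocation, hc$allocation)
  expect_identical(sa$trace, hc$trace)
})

test_that("annealing tracks the best-so-far allocation", {
  for (seed in 1:5) {
    inst <- make_oracle_instance(seed + 20)
    fit <- allocate_genes(inst$membership, inst$expression, method = "sa",
                          iterations = 500, seed = seed)
    expect_true(is_valid_allocation(fit$allocation, inst$membership,
                                    fit$states))
    expect_equal(fit$fitness,
                 total_fitness(fit$allocation, inst$membership, fit$states))
    expect_equal(fit$fitness, max(fit$trace))
    expect_true(all(diff(fit$trace) >= 0))  # best-so-far is monotone
  }
})

test_that("hill climbing can stall in the crafted local maximum that annealing escapes", {
  trap <- make_trap_instance()
  best <- oracle_max_fitness(trap$membership, trap$states)
  expect_identical(best, 10)
  hc <- sapply(1:30, function(s) {
    allocate_genes(trap$membership, trap$expression, method = "hc",
                   iterations = 2000, seed = s)$fitness
  })
  sa <- sapply(1:30, function(s) {
    allocate_genes(trap$membership, trap$expression, method = "sa",
                   iterations = 2000, seed = s)$fitness
  })
  expect_true(all(hc <= best))
  expect_true(any(hc < best))        # the local maximum at fitness 9
  expect_true(mean(sa == best) >= 0.95)
})

test_that("mutation flips about one free gene per call and stays valid", {
  inst <- make_oracle_instance(8)
  mem <- inst$membership
  n_free <- sum(inst$states$state != 0 & mem$n_members > 1)
  A <- random_allocation(mem, inst$states, seed = 1)
  set.seed(500)
  n_changed <- replicate(2000, {
    B <- mutate_allocation(A, mem, inst$states)
    sum(rowSums(abs(B - A)) > 0)
  })
  expect_equal(mean(n_changed), 1, tolerance = 0.1)  # n_free * 1/n_free
  expect_lte(max(n_changed), n_free)
  for (s in 1:20) {
    B <- mutate_allocation(A, mem, inst$states, seed = s)
    expect_true(is_valid_allocation(B, mem, inst$states))
  }
})

test_that("mutation redraws flips that would empty a row", {
  # one free gene allocated to exactly one of two pathways: the only legal
  # mutation is the add, never the emptying removal
  mem <- pathway_membership(data.frame(gene = c("m", "m", "s"),
                                       pathway = c("A", "B", "A")))
  st <- gene_states(data.frame(gene = c("m", "s"), log2_ratio = c(2, 2)), mem)
  A <- full_allocation(mem, st)
  A["m", "B"] <- 0L
  set.seed(7)
  for (rep in 1:50) {
    B <- mutate_allocation(A, mem, st)
    expect_gte(sum(B["m", ]), 1L)
  }
  # nothing to mutate -> unchanged
  mem2 <- pathway_membership(data.frame(gene = "s", pathway = "A"))
  st2 <- gene_states(data.frame(gene = "s", log2_ratio = 2), mem2)
  A2 <- full_allocation(mem2, st2)
  expect_identical(mutate_allocation(A2, mem2, st2, seed = 1), A2)
})

test_that("crossover swaps whole gene rows around a single cut point", {
  inst <- make_oracle_instance(5)
  a <- random_allocation(inst$membership, inst$states, seed = 1)
  b <- random_allocation(inst$membership, inst$states, seed = 2)
  for (s in 1:20) {
    kids <- crossover_allocation(a, b, seed = s)
    for (kid in kids) {
      expect_true(is_valid_allocation(kid, inst$membership, inst$states))
      for (i in seq_len(nrow(a))) {
        expect_true(identical(kid[i, ], a[i, ]) || identical(kid[i, ], b[i, ]))
      }
    }
    # complementary inheritance
    from_a <- sapply(seq_len(nrow(a)),
                     function(i) identical(kids$child_a[i, ], a[i, ]))
    from_b <- sapply(seq_len(nrow(a)),
                     function(i) identical(kids$child_b[i, ], b[i, ]))
    differ <- sapply(seq_len(nrow(a)), function(i) !identical(a[i, ], b[i, ]))
    expect_identical(from_a[differ], from_b[differ])
  }
  # a one-gene chromosome forces the cut to the end: children equal parents
  mem1 <- pathway_membership(data.frame(gene = c("m", "m"),
                                        pathway = c("A", "B")))
  st1 <- gene_states(data.frame(gene = "m", log2_ratio = 2), mem1)
  a1 <- random_allocation(mem1, st1, seed = 1)
  b1 <- matrix(c(1L, 1L), 1, dimnames = dimnames(a1))
  kids1 <- crossover_allocation(a1, b1, seed = 1)
  expect_identical(kids1$child_a, a1)
  expect_identical(kids1$child_b, b1)
})

test_that("the genetic algorithm is elitist and returns valid optima", {
  for (seed in 1:5) {
    inst <- make_oracle_instance(seed + 40)
    fit <- allocate_genes(inst$membership, inst$expression, method = "ga",
                          pop_size = 20, generations = 40, seed = seed)
    expect_true(all(diff(fit$trace) >= 0))
    expect_true(is_valid_allocation(fit$allocation, inst$membership,
                                    fit$states))
    expect_equal(fit$fitness,
                 total_fitness(fit$allocation, inst$membership, fit$states))
  }
  expect_error(
    allocate_genes(make_oracle_instance(1)$membership,
                   make_oracle_instance(1)$expression,
                   method = "ga", pop_size = 1, seed = 1),
    "pop_size"
  )
})

test_that("equal seeds give bit-identical search results", {
  inst <- make_oracle_instance(12)
  for (m in c("hc", "sa", "ga")) {
    f1 <- allocate_genes(inst$membership, inst$expression, method = m,
                         iterations = 200, pop_size = 12, generations = 15,
                         seed = 33)
    f2 <- allocate_genes(inst$membership, inst$expression, method = m,
                         iterations = 200, pop_size = 12, generations = 15,
                         seed = 33)
    expect_identical(f1$allocation, f2$allocation)
    expect_identical(f1$trace, f2$trace)
    expect_identical(f1$fitness, f2$fitness)
  }
})

test_that("module-mode searches never co-allocate an opposing pair", {
  inst <- make_module_instance()
  ja <- "m_glycolysis"; jb <- "m_gluconeogenesis"
  for (seed in 1:6) {
    for (m in c("hc", "sa", "ga")) {
      fit <- allocate_genes(inst$membership, inst$expression, method = m,
                            opposing = inst$opposing, iterations = 400,
                            pop_size = 16, generations = 25, seed = seed)
      expect_identical(fit$mode, "module")
      expect_true(all(fit$allocation[, ja] * fit$allocation[, jb] == 0L))
      st <- gene_states(inst$expression, inst$membership)
      expect_true(is_valid_allocation(fit$allocation, inst$membership, st,
                                      inst$opposing))
    }
  }
})

test_that("fitness traces have the advertised length and evaluation counts", {
  inst <- make_oracle_instance(2)
  hc <- allocate_genes(inst$membership, inst$expression, method = "hc",
                       iterations = 123, seed = 1)
  expect_identical(length(hc$trace), 123L)
  tr <- fitness_trace(hc)
  expect_identical(tr$fitness_evals, tr$step)
  ga <- allocate_genes(inst$membership, inst$expression, method = "ga",
                       pop_size = 10, generations = 7, seed = 1)
  expect_identical(length(ga$trace), 7L)
  expect_true(all(fitness_trace(ga)$fitness_evals == (1:7) * 20))
})
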