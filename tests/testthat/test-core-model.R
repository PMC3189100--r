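test_that("discretisation applies strict thresholds to log2 ratios", {
  # tryptophan-enrichment fixture values
  expect_identical(discretize(5.8490, 1), 1L)   # trpS, strongly up
  expect_identical(discretize(-0.4370, 1), 0L)  # katE, stable
  expect_identical(discretize(-1.8120, 1), -1L) # yqeF, down
  # exactly at the threshold is stable on both sides
  expect_identical(discretize(c(1, -1), 1), c(0L, 0L))
  expect_identical(discretize(c(1 + 1e-9, -1 - 1e-9), 1), c(1L, -1L))
})

test_that("discretisation is odd-symmetric and rejects bad input", {
  set.seed(1)
  for (rep in 1:20) {
    g <- rnorm(50, sd = 2)
    c0 <- runif(1, 0.2, 2)
    expect_identical(discretize(-g, c0), -discretize(g, c0))
  }
  expect_error(discretize(c(1, NA), 1), "finite")
  expect_error(discretize(c(1, Inf), 1), "finite")
  expect_error(discretize(1, 0), "positive")
  expect_error(discretize(1, -1), "positive")
})

test_that("gene_states aligns expression to the membership universe", {
  mem <- pathway_membership(data.frame(
    gene = c("a", "b", "b", "c"),
    pathway = c("P1", "P1", "P2", "P2")
  ))
  expr <- data.frame(gene = c("a", "b", "zzz"), log2_ratio = c(2, -3, 9))
  expect_message(st <- gene_states(expr, mem, 1), "absent")
  expect_identical(st$gene, c("a", "b", "c"))
  expect_identical(st$state, c(1L, -1L, 0L))   # unmeasured c is stable
  expect_true(is.na(st$log2_ratio[3]))
  expect_error(
    gene_states(data.frame(gene = c("a", "a"), log2_ratio = c(1, 2)), mem),
    "duplicate"
  )
})

test_that("allocation validity enforces the membership and coverage rules", {
  mem <- pathway_membership(data.frame(
    gene = c("m", "m", "s", "q"),
    pathway = c("P1", "P2", "P1", "P2")
  ))
  st <- gene_states(
    data.frame(gene = c("m", "s", "q"), log2_ratio = c(2, 2, 0.5)), mem
  )
  full <- full_allocation(mem, st)
  expect_true(is_valid_allocation(full, mem, st))
  # stable gene q must not be allocated
  bad <- full; bad["q", "P2"] <- 1L
  expect_false(is_valid_allocation(bad, mem, st))
  # expressed multi-membership gene with an all-zero row is rejected
  bad <- full; bad["m", ] <- 0L
  expect_false(is_valid_allocation(bad, mem, st))
  # an entry outside the membership snapshot is rejected
  bad <- full; bad["s", "P2"] <- 1L
  expect_false(is_valid_allocation(bad, mem, st))
  # expressed single-membership gene cannot lose its pathway
  bad <- full; bad["s", "P1"] <- 0L
  expect_false(is_valid_allocation(bad, mem, st))
})

test_that("module-mode validity bans co-allocation to opposing pairs", {
  inst <- make_module_instance()
  st <- gene_states(inst$expression, inst$membership)
  full <- full_allocation(inst$membership, st)
  # shared expressed genes sit in both opposing modules under full membership
  expect_true(is_valid_allocation(full, inst$membership, st))
  expect_false(is_valid_allocation(full, inst$membership, st, inst$opposing))
  ra <- random_allocation(inst$membership, st, inst$opposing, seed = 5)
  expect_true(is_valid_allocation(ra, inst$membership, st, inst$opposing))
})

test_that("random allocations are valid, seed-reproducible, and fix single genes", {
  for (seed in 1:10) {
    inst <- make_oracle_instance(seed)
    a1 <- random_allocation(inst$membership, inst$states, seed = seed * 7)
    a2 <- random_allocation(inst$membership, inst$states, seed = seed * 7)
    expect_identical(a1, a2)
    expect_true(is_valid_allocation(a1, inst$membership, inst$states))
    single <- inst$membership$n_members == 1L
    expect_identical(a1[single, , drop = FALSE],
                     inst$membership$incidence[single, , drop = FALSE])
  }
})

test_that("a two-pathway gene's random row is uniform over the 3 valid strings", {
  # 900 exchangeable genes x 100 draws = 90,000 rows
  sets <- data.frame(
    gene = rep(sprintf("g%03d", 1:900), each = 2),
    pathway = rep(c("P1", "P2"), 900)
  )
  mem <- pathway_membership(sets)
  expr <- data.frame(gene = mem$genes, log2_ratio = 2)
  st <- gene_states(expr, mem)
  set.seed(2024)
  codes <- integer(0)
  for (rep in 1:100) {
    A <- random_allocation(mem, st)
    codes <- c(codes, A[, 1] + 2L * A[, 2])  # 1 = "10", 2 = "01", 3 = "11"
  }
  n <- length(codes)
  expect_identical(n, 90000L)
  expect_true(all(codes %in% 1:3))  # never the all-zero string
  freq <- tabulate(codes, 3L)
  sigma <- sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(freq - n / 3) < 3 * sigma))
})
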