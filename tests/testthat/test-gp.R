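test_that("crossover of two terminals exchanges the roots at most", {
  set.seed(31)
  kids <- crossover(gp_terminal(1), gp_terminal(2))
  expect_setequal(vapply(kids, deparse_formula, character(1)),
                  c("X1", "X2"))
})

test_that("crossover and mutation never break the depth cap", {
  set.seed(32)
  parents <- replicate(20, random_tree(8, "full"), simplify = FALSE)
  for (i in 1:250) {
    pair <- sample(20, 2)
    kids <- crossover(parents[[pair[1]]], parents[[pair[2]]], max_depth = 10)
    expect_lte(max(tree_depth(kids[[1]]), tree_depth(kids[[2]])), 10)
    expect_lte(tree_depth(mutate(parents[[pair[1]]], max_depth = 10)), 10)
  }
})

test_that("node count is conserved when equal-size subtrees are swapped", {
  set.seed(33)
  a <- random_tree(5, "full")
  b <- random_tree(5, "full")
  for (i in 1:50) {
    kids <- crossover(a, b)
    expect_equal(tree_size(kids[[1]]) + tree_size(kids[[2]]),
                 tree_size(a) + tree_size(b))
  }
})

test_that("operators are reproducible under a fixed seed", {
  a <- parse_formula("(plus (sin X1) (times X2 X3))")
  set.seed(34); m1 <- mutate(a)
  set.seed(34); m2 <- mutate(a)
  expect_equal(m1, m2)
  set.seed(34); c1 <- crossover(a, a)
  set.seed(34); c2 <- crossover(a, a)
  expect_equal(c1, c2)
})

test_that("fitness is the misclassified fraction of the validation group", {
  # references at 0 (spike) and 10 (nonspike); validation X4 values chosen
  # so the identity tree on X4 classifies 8 of 10 correctly
  ref <- x4_feature_table(5, mu_spike = 0, mu_nonspike = 10, sd = 1e-6)
  val <- x4_feature_table(5, mu_spike = 0, mu_nonspike = 10, sd = 1e-6)
  val$X4[c(1, 6)] <- c(10, 0)  # one error per class
  ctx <- fitness_context(ref, val, k = 1)
  expect_equal(gp_fitness(gp_terminal(4), ctx), 0.2)
  val2 <- x4_feature_table(5, mu_spike = 0, mu_nonspike = 10, sd = 1e-6)
  expect_equal(gp_fitness(gp_terminal(4), fitness_context(ref, val2, k = 1)),
               0)
})

test_that("fitness context enforces balanced groups", {
  ref <- x4_feature_table(5)
  bad <- ref[-1, ]
  expect_error(fitness_context(bad, ref, k = 1), "equal spike and nonspike")
  expect_error(fitness_context(ref, ref[0, ], k = 1), "no segments")
  expect_warning(fitness_context(ref, ref, k = 100), "clamping")
})

test_that("a short evolution run keeps the engine's invariants", {
  set.seed(36)
  ctx <- x4_context(n_per_class = 20, k = 5)
  gens <- list()
  cfg <- gp_config(population_size = 10L, n_generations = 15L, rng_seed = 99)
  res <- evolve_formula(ctx, cfg, on_generation = function(g, pop, fit, pc, pm)
    gens[[g]] <<- list(n = length(pop),
                       max_depth = max(vapply(pop, tree_depth, integer(1))),
                       psum = pc + pm))
  expect_length(res$trace, 16L)
  expect_true(all(diff(res$trace) <= 0))
  expect_true(all(vapply(gens, `[[`, numeric(1), "n") == 10L))
  expect_true(all(vapply(gens, `[[`, numeric(1), "max_depth") <= 25L))
  expect_equal(vapply(gens, `[[`, numeric(1), "psum"), rep(1, 15L))
  # elitism: the final best cannot be worse than the initial best
  expect_lte(res$best_fitness, res$trace[1])
  expect_equal(res$best_fitness, gp_fitness(res$best, ctx))
})

test_that("evolution is bit-reproducible under a fixed seed", {
  set.seed(37)
  ctx <- x4_context(n_per_class = 15, k = 5)
  cfg <- gp_config(population_size = 8L, n_generations = 10L, rng_seed = 7)
  r1 <- evolve_formula(ctx, cfg)
  r2 <- evolve_formula(ctx, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(deparse_formula(r1$best), deparse_formula(r2$best))
  expect_identical(r1$p_mutation, r2$p_mutation)
})

test_that("the adaptive schedule raises mutation on stagnation and resets", {
  set.seed(38)
  ctx <- x4_context(n_per_class = 10, k = 1)
  cfg <- gp_config(population_size = 6L, n_generations = 12L, rng_seed = 3)
  res <- evolve_formula(ctx, cfg)
  # replay the stated recurrence from the fitness trace
  pm <- cfg$p_mutation_init
  expected <- numeric(12L)
  for (g in 1:12) {
    pm <- if (res$trace[g + 1] < res$trace[g]) cfg$p_mutation_init
          else min(pm + cfg$adaptation_step, cfg$p_mutation_cap)
    expected[g] <- pm
  }
  expect_equal(res$p_mutation, expected)
  expect_equal(res$p_crossover + res$p_mutation, rep(1, 12L))
})

test_that("terminal subsets restrict every individual in the population", {
  set.seed(39)
  ctx <- x4_context(n_per_class = 10, k = 1)
  cfg <- gp_config(population_size = 6L, n_generations = 5L,
                   terminal_subset = c(4L, 6L), rng_seed = 11)
  leaves_of <- function(tree) unlist(lapply(seq_len(tree_size(tree)),
    function(j) {
      n <- spikegp:::get_subtree(tree, j)
      if (n$type == "t") n$ix
    }))
  res <- evolve_formula(ctx, cfg, on_generation = function(g, pop, ...)
    for (tr in pop) expect_true(all(leaves_of(tr) %in% c(4L, 6L))))
  expect_true(all(leaves_of(res$best) %in% c(4L, 6L)))
})
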