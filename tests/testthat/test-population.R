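# Iteration loop: conjugation, division, culling, and whole-run invariants.

test_that("founding population is uniform, balanced and maximally fit", {
  p <- sim_params(pop_size = 25)
  pop <- initialize_population(p)
  expect_length(pop$X, 25)
  expect_true(all(pop$X == p$X0) && all(pop$E == 0) &&
                all(pop$G == 0) && all(pop$A == 0))
  expect_equal(pop$N,
               rep(chromosome_number_from_elimination(0, p$N0), 25))
  expect_equal(total_fitness(as.data.frame(pop), p), rep(1, 25))
  expect_length(initialize_population(sim_params(pop_size = 1))$X, 1)
})

test_that("mutation draws are clamped to the violated bound, not resampled", {
  expect_equal(mutate_clamped(5, 0), 5)                    # sd = 0: unchanged
  expect_equal(mutate_clamped(1.5, 0, lo = 0, hi = 0.98), 0.98)
  expect_equal(mutate_clamped(-3, 0, lo = 0), 0)
  set.seed(1)
  draws <- mutate_clamped(rep(0.97, 5000), 0.05, lo = 0, hi = 0.98)
  expect_true(all(draws >= 0 & draws <= 0.98))
  expect_true(any(draws == 0.98))  # upper-bound mass from clamping
  expect_error(mutate_clamped(1, -1), "sd")
  expect_error(mutate_clamped(1, 1, lo = 2, hi = 1), "lo")
})

test_that("immature cells never conjugate; conjugation resets age and remaps N", {
  p <- sim_params(S = 1, M = 15)
  cell <- list(X = 30, E = 0.5, N = chromosome_number_from_elimination(0.5, 50),
               G = 14, A = 40)
  set.seed(2)
  for (i in 1:50) expect_false(attempt_conjugation(cell, p)$conjugated)
  cell$G <- 15
  res <- attempt_conjugation(cell, p)  # S = 1: certain
  expect_true(res$conjugated)
  expect_equal(res$cell$G, 0)
  expect_equal(res$cell$A, 0)
  expect_equal(res$cell$N,
               chromosome_number_from_elimination(res$cell$E, p$N0))
  expect_true(res$cell$E >= 0 && res$cell$E <= 0.98)
  expect_true(res$cell$X >= 0)
})

test_that("division waits for iteration age I, clones faithfully, and ages cells", {
  p <- sim_params(I = 2)
  fresh <- list(X = 10, E = 0, N = 50, G = 0, A = 0)  # fitness 1
  set.seed(3)
  res <- attempt_division(fresh, p)
  expect_null(res$daughter)          # too young to divide
  expect_equal(res$cell$A, 1)
  expect_equal(res$cell$G, 0)
  ready <- list(X = 10, E = 0, N = 50, G = 0, A = 2)  # F = 1: certain
  res <- attempt_division(ready, p)
  expect_false(is.null(res$daughter))
  expect_identical(res$daughter, res$cell)            # identical copy
  expect_equal(res$cell$G, 1)
  expect_equal(res$cell$A, 3)
  dead <- list(X = 0, E = 0, N = 50, G = 1, A = 10)   # F = 0
  for (i in 1:20) {
    res <- attempt_division(dead, p)
    expect_null(res$daughter)
    dead <- res$cell
  }
  expect_equal(dead$A, 30)
  expect_equal(dead$G, 1)
})

test_that("culling keeps exactly pop_size cells, uniformly at random", {
  p <- sim_params(pop_size = 10)
  pop <- initialize_population(p)
  pop$X <- as.numeric(1:10)
  expect_equal(cull(pop, p)$X, as.numeric(1:10))  # pool <= target: unchanged
  big <- pop
  for (f in c("X", "E", "N", "G", "A")) big[[f]] <- rep(pop[[f]], 2)
  big$X <- as.numeric(1:20)
  set.seed(4)
  culled <- cull(big, p)
  expect_length(culled$X, 10)
  # selection frequencies uniform across the pool (chi-square)
  counts <- numeric(20)
  for (i in 1:2000) {
    kept <- cull(big, p)$X
    counts[kept] <- counts[kept] + 1
  }
  chi <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chi, qchisq(0.999, df = 19))
  empty <- initialize_population(p)
  for (f in c("X", "E", "N", "G", "A")) empty[[f]] <- numeric(0)
  expect_error(cull(empty, p), "extinct")
})

test_that("population size equals pop_size after every iteration", {
  p <- sim_params(pop_size = 60, n_iter = 1, seed = 5, M = 2, I = 0, S = 0.5)
  set.seed(5)
  pop <- initialize_population(p)
  for (it in 1:60) {
    pop <- macevol:::step_population(pop, p)
    expect_length(pop$X, 60)
    expect_true(all(pop$A >= pop$G))
  }
})

test_that("heritable traits change only at conjugation", {
  # conjugation blocked: X, E, N frozen at founding values for the whole run
  p <- sim_params(pop_size = 50, n_iter = 400, seed = 6, M = 1e9)
  sim <- run_simulation(p, record_every = 50)
  expect_true(all(sim$summary$mean_X == p$X0))
  expect_true(all(sim$summary$mean_E == 0))
  expect_true(all(sim$summary$mean_N == p$N0))
  expect_true(all(sim$summary$sd_X == 0))
  # mutation disabled: conjugation occurs but distributions are invariant
  p0 <- sim_params(pop_size = 50, n_iter = 400, seed = 7,
                   Sd_copy = 0, Sd_elim = 0, M = 3)
  sim0 <- run_simulation(p0, record_every = 50)
  expect_true(all(sim0$summary$mean_X == p0$X0))
  expect_true(all(sim0$summary$mean_E == 0))
  expect_true(all(sim0$summary$mean_N == p0$N0))
})

test_that("mean imbalance fitness declines as vegetative generations accumulate", {
  # with conjugation blocked, mean G can only grow and F_imb can only sink
  p <- sim_params(pop_size = 100, n_iter = 120, seed = 8, M = 1e9)
  sim <- run_simulation(p, record_every = 20)
  fimb <- sim$summary$mean_Fimb
  expect_equal(fimb[1], 1)
  # small upward wiggles possible from uniform culling; trend is downward
  expect_true(all(diff(fimb) <= 0.02))
  expect_lt(fimb[length(fimb)], 0.9)
})

test_that("runs are exactly reproducible from the seed", {
  p <- tiny_params()
  a <- run_simulation(p, record_every = 10)
  b <- run_simulation(p, record_every = 10)
  expect_identical(a$summary, b$summary)
  expect_identical(a$final, b$final)
  p2 <- tiny_params(seed = 12)
  c2 <- run_simulation(p2, record_every = 10)
  expect_false(identical(a$summary, c2$summary))
})

test_that("a zero-iteration run reports only the founding state", {
  sim <- run_simulation(sim_params(pop_size = 20, n_iter = 0, seed = 1))
  expect_equal(nrow(sim$summary), 1)
  expect_equal(sim$summary$mean_X, 10)
  expect_equal(sim$summary$mean_F, 1)
  expect_false(sim$collapsed)
})
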