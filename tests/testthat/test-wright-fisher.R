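test_that("population initialization honors the configured start", {
  cfg <- evolution_config(population_size = 1000, group_size = 10,
                          mode = "evolving_sharing")
  withr::with_seed(1, {
    pop <- initialize_population(cfg)
    expect_equal(dim(pop$strategies), c(1000, 10))
    expect_true(all(pop$strategies >= 0 & pop$strategies <= 1))
    expect_equal(mean(pop$strategies), 0.5, tolerance = 0.01)
    expect_true(all(pop$cell_betas == 0))  # sharing starts absent
  })
  withr::with_seed(2, p1 <- initialize_population(cfg))
  withr::with_seed(2, p2 <- initialize_population(cfg))
  expect_identical(p1, p2)
})

test_that("strategy mutation kernel has sd ~ v/10, truncated to [0,1]", {
  withr::with_seed(5, {
    draws <- replicate(20000, mutate_strategy(c(0.5, 0.9))[1])
    expect_equal(sd(draws), 0.05, tolerance = 0.05)
    expect_equal(mean(draws), 0.5, tolerance = 0.005)
    many <- replicate(2000, mutate_strategy(c(0.02, 0.98)))
    expect_true(all(many >= 0 & many <= 1))
    # exact zero is pinned (sd = 0)
    expect_identical(mutate_strategy(c(0, 0.5))[1], 0)
  })
})

test_that("beta mutation changes exactly one cell and can escape zero", {
  withr::with_seed(6, {
    row <- c(0.4, 0.4, 0.4, 0.4)
    out <- mutate_beta(row)
    expect_equal(sum(out != row), 1)
    # degenerate kernel without a floor: all-zero row is absorbing
    expect_identical(mutate_beta(rep(0, 4), sd_floor = 0), rep(0, 4))
    # with the default floor, neutral drift leaves zero quickly
    b <- rep(0, 4)
    steps <- 0
    while (mean(b) < 0.05 && steps < 1e4) {
      b <- mutate_beta(b)
      steps <- steps + 1
    }
    expect_lt(steps, 1e4)
  })
})

test_that("rank selection weights offspring linearly in fitness rank", {
  withr::with_seed(7, {
    # two groups with fitnesses (1, 2): ranks 1 and 2, probabilities 1/3, 2/3
    picks <- replicate(30000, select_offspring(c(1, 2))[1])
    expect_equal(mean(picks == 2), 2 / 3, tolerance = 0.02)
    # ties share averaged rank: uniform when all fitnesses equal
    u <- table(replicate(6000, select_offspring(c(3, 3, 3))[1]))
    expect_equal(as.vector(u) / 6000, rep(1 / 3, 3), tolerance = 0.05)
    # expected offspring of the top group out of P is 2P/(P+1)
    P <- 20
    kids <- replicate(4000, sum(select_offspring(seq_len(P)) == P))
    expect_equal(mean(kids), 2 * P / (P + 1), tolerance = 0.05)
  })
})

test_that("identical seeds give bit-identical runs; sizes stay constant", {
  t <- make_topology("ring", 10)
  cfg <- evolution_config(population_size = 60, generations = 40, seed = 11,
                          alpha = 1.1)
  e1 <- run_evolution(cfg, t)
  e2 <- run_evolution(cfg, t)
  expect_identical(e1$trajectory, e2$trajectory)
  expect_identical(e1$state$strategies, e2$state$strategies)
  expect_equal(dim(e1$state$strategies), c(60, 10))
  expect_true(all(e1$state$strategies >= 0 & e1$state$strategies <= 1))
  expect_equal(nrow(e1$trajectory), 41)
  expect_error(run_evolution(cfg, make_topology("ring", 5)), "group_size")
})

test_that("without mutation, diversity only shrinks and fitness drifts up", {
  t <- make_topology("ring", 10)
  cfg <- evolution_config(population_size = 80, generations = 60,
                          mutation_probability = 0, seed = 13, alpha = 0.9)
  ev <- run_evolution(cfg, t)
  tr <- ev$trajectory
  expect_gte(dplyr::last(tr$mean_fitness), tr$mean_fitness[1])
  # no new variants: final population is a subset of initial rows
  n_unique <- nrow(unique(ev$state$strategies))
  expect_lte(n_unique, 80)
  expect_lt(n_unique, 10)  # heavy coalescence after 60 generations
  # max fitness can never exceed the best initial group
  expect_lte(max(tr$max_fitness), tr$max_fitness[1] + 1e-12)
})

test_that("evolution respects the sharing regime", {
  t <- make_topology("ring", 10)
  # no sharing: specialization does not evolve
  cfg0 <- evolution_config(population_size = 150, generations = 150,
                           alpha = 0.7, beta = 0, seed = 17)
  ev0 <- run_evolution(cfg0, t)
  expect_lt(dplyr::last(ev0$trajectory$mean_specialization), 0.2)

  # strong sharing, accelerating returns: specialists take over
  cfg1 <- evolution_config(population_size = 150, generations = 200,
                           alpha = 1.2, beta = 1, seed = 19)
  ev1 <- run_evolution(cfg1, t)
  expect_gt(dplyr::last(ev1$trajectory$mean_specialization), 0.5)
})

test_that("evolving-sharing mode grows beta away from zero under selection", {
  t <- make_topology("ring", 10)
  cfg <- evolution_config(population_size = 200, generations = 400,
                          mode = "evolving_sharing", alpha = 1.2, seed = 23)
  ev <- run_evolution(cfg, t)
  tr <- ev$trajectory
  expect_equal(tr$mean_beta[1], 0)
  expect_gt(dplyr::last(tr$mean_beta), 0.01)
  expect_true(all(ev$state$cell_betas >= 0 & ev$state$cell_betas <= 1))
})

test_that("evolution results tidy, glance, and autoplot", {
  cfg <- evolution_config(population_size = 30, generations = 10, seed = 3)
  ev <- run_evolution(cfg, make_topology("ring", 10))
  expect_identical(tidy(ev), ev$trajectory)
  g <- glance(ev)
  expect_equal(g$generations, 10L)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})
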