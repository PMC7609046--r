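test_that("sharing matrix rows sum to 1 with the prescribed entries", {
  r4 <- make_topology("ring", 4)
  c1 <- build_sharing(r4, 1)
  expect_equal(unname(c1), matrix(c(
    1/3, 1/3, 0,   1/3,
    1/3, 1/3, 1/3, 0,
    0,   1/3, 1/3, 1/3,
    1/3, 0,   1/3, 1/3), nrow = 4, byrow = TRUE))

  # no sharing, and isolated cells at any beta, give the identity
  expect_equal(build_sharing(r4, 0), diag(4))
  expect_equal(build_sharing(make_topology("disconnected", 5), 0.7), diag(5))

  # row sums and diagonal positivity across families and beta values
  for (t in list(r4, make_topology("balanced_bipartite", 8),
                 make_topology("filament", 6),
                 make_topology("erdos_renyi", 9, p = 0.4, seed = 3))) {
    for (b in c(0, 0.3, 1)) {
      cm <- build_sharing(t, b)
      expect_equal(rowSums(cm), rep(1, t$n_cells))
      expect_true(all(diag(cm) > 0))
      expect_true(all(cm >= 0))
    }
  }
  expect_error(build_sharing(r4, 1.2), "\\[0, 1\\]")
})

test_that("per-cell beta produces the giver-indexed rows", {
  f3 <- make_topology("filament", 3)
  cm <- build_sharing(f3, c(0, 0.5, 1))
  ni <- c(2, 3, 2)
  expect_equal(diag(cm), 1 - c(0, 0.5, 1) + c(0, 0.5, 1) / ni)
  expect_equal(cm[2, 1], 0.5 / 3)  # middle cell gives beta_1/n_1
  expect_equal(cm[1, 2], 0)        # cell 0 keeps everything
  expect_equal(rowSums(cm), rep(1, 3))
})

test_that("viability returns are incoming column sums", {
  r4 <- make_topology("ring", 4)
  c1 <- build_sharing(r4, 1)
  # alternating specialists: fecundity cells receive 1/3 from each viability
  # neighbor, viability cells keep 1/3 of their own output
  expect_equal(viability_returns(c(1, 0, 1, 0), c1, 1),
               c(1/3, 2/3, 1/3, 2/3))
  # conservation with everyone at full investment: each cell of a regular
  # graph receives exactly 1; on irregular graphs only the total is conserved
  cm_reg <- build_sharing(make_topology("ring", 7), 0.8)
  expect_equal(viability_returns(rep(1, 7), cm_reg, 1), rep(1, 7))
  cm <- build_sharing(make_topology("erdos_renyi", 7, p = 0.5, seed = 1), 0.8)
  expect_equal(sum(viability_returns(rep(1, 7), cm, 1)), 7)
  # brute-force double-loop oracle on a random configuration
  withr::with_seed(11, {
    v <- runif(7)
    expect_equal(viability_returns(v, cm, 2),
                 brute_viability_returns(v, cm, 2))
  })
})

test_that("group fitness reproduces the four-cell ring worked example", {
  c1 <- build_sharing(make_topology("ring", 4), 1)
  expect_equal(group_fitness(rep(0.5, 4), c1, 1), 1)
  expect_equal(group_fitness(c(1, 0, 1, 0), c1, 1), 4 / 3)
  expect_equal(group_fitness(rep(0.5, 4), c1, 0.9), 4 * 0.5^1.8)
  # the generalist value is beta-independent on a regular graph
  c05 <- build_sharing(make_topology("ring", 4), 0.5)
  expect_equal(group_fitness(rep(0.5, 4), c05, 0.9), 4 * 0.5^1.8)
})

test_that("balanced-bipartite alternating specialists give W = 25/6 at N=10", {
  bb <- make_topology("balanced_bipartite", 10)
  cb <- build_sharing(bb, 1)
  v <- c(rep(1, 5), rep(0, 5))
  for (a in c(0.7, 1, 1.3)) {
    expect_equal(group_fitness(v, cb, a), 25 / 6)
    expect_equal(group_fitness(v, cb, a), brute_fitness(v, cb, a))
  }
})

test_that("fitness matches the brute-force oracle and graph relabeling", {
  withr::with_seed(21, {
    t <- make_topology("erdos_renyi", 8, p = 0.5, seed = 5)
    cm <- build_sharing(t, 0.6)
    for (rep_i in 1:5) {
      v <- runif(8)
      a <- runif(1, 0.5, 1.5)
      expect_equal(group_fitness(v, cm, a), brute_fitness(v, cm, a))
    }
    # relabeling invariance: permute cells jointly in topology and strategy
    perm <- sample(8)
    edges_p <- matrix(match(t$edges + 1L, perm) - 1L, ncol = 2)
    tp <- new_topology(8, edges_p)
    v <- runif(8)
    expect_equal(group_fitness(v[perm], build_sharing(tp, 0.6), 0.8),
                 group_fitness(v, cm, 0.8))
  })
})

test_that("conservation: W = N/4 for any topology at alpha=1, v=1/2", {
  for (t in list(make_topology("ring", 6), make_topology("complete", 7),
                 make_topology("kary_tree", 9),
                 make_topology("erdos_renyi", 11, p = 0.3, seed = 2))) {
    for (b in c(0.2, 1)) {
      expect_equal(group_fitness(rep(0.5, t$n_cells),
                                 build_sharing(t, b), 1),
                   t$n_cells / 4)
    }
  }
})

test_that("ring closed forms equal direct evaluation over parameter grids", {
  for (n in c(4, 6, 8, 10)) {
    t <- make_topology("ring", n)
    spec <- rep_len(c(0, 1), n)
    for (a in c(0.6, 0.9, 1, 1.3)) {
      for (b in c(0.25, 0.5, 1)) {
        cm <- build_sharing(t, b)
        expect_equal(closed_form_fitness("ring_specialist", n, a, b),
                     group_fitness(spec, cm, a))
        expect_equal(closed_form_fitness("ring_generalist", n, a, b),
                     group_fitness(rep(0.5, n), cm, a))
      }
    }
  }
  expect_equal(closed_form_fitness("ring_specialist", 4, beta = 1), 4 / 3)
  expect_equal(closed_form_fitness("ring_specialist", 10, beta = 0.5), 5 / 3)
  expect_equal(closed_form_fitness("ring_generalist", 4, alpha = 1), 1)
  expect_equal(closed_form_fitness("disconnected_optimum", 10, alpha = 0.8),
               10 * 0.5^1.6)
  expect_error(closed_form_fitness("ring_specialist", 5), "even")
})

test_that("gradient vanishes at the generalist point iff sharing is symmetric", {
  for (t in list(make_topology("ring", 6), make_topology("complete", 5),
                 make_topology("balanced_bipartite", 8))) {
    g <- fitness_gradient(rep(0.5, t$n_cells), build_sharing(t, 0.7), 0.9)
    expect_equal(g, rep(0, t$n_cells))
  }
  # filament degrees differ, c != t(c), gradient nonzero
  g <- fitness_gradient(rep(0.5, 4),
                        build_sharing(make_topology("filament", 4), 0.7), 0.9)
  expect_gt(max(abs(g)), 1e-3)
})

test_that("gradient and Hessian match finite differences on random interiors", {
  withr::with_seed(31, {
    cases <- list(list(t = make_topology("ring", 6), a = 0.8, b = 0.6),
                  list(t = make_topology("ring", 5), a = 0.9, b = 1),
                  list(t = make_topology("filament", 6), a = 1.2, b = 0.8),
                  list(t = make_topology("erdos_renyi", 7, p = 0.5, seed = 9),
                       a = 1.1, b = 0.5))
    for (cs in cases) {
      cm <- build_sharing(cs$t, cs$b)
      v <- random_interior_strategy(cs$t$n_cells)
      g <- fitness_gradient(v, cm, cs$a)
      expect_equal(g, fd_gradient(v, cm, cs$a), tolerance = 1e-6)
      h <- fitness_hessian(v, cm, cs$a)
      expect_identical(h, base::t(h))
      expect_equal(h, fd_hessian(v, cm, cs$a), tolerance = 1e-5)
    }
  })
})

test_that("boundary strategies give signed-infinite derivatives, not errors", {
  cm <- build_sharing(make_topology("ring", 4), 1)
  g <- fitness_gradient(c(0, 1, 0.5, 0.5), cm, 0.8)
  expect_true(any(is.infinite(g)))
  expect_silent(fitness_hessian(c(0, 1, 0.5, 0.5), cm, 0.8))
})

test_that("two-good fitness reduces to one-good and matches hand values", {
  r4 <- make_topology("ring", 4)
  c1 <- build_sharing(r4, 1)
  withr::with_seed(41, {
    v <- runif(4)
    expect_equal(group_fitness_two_goods(v, c1, diag(4), 0.9),
                 group_fitness(v, c1, 0.9))
  })
  expect_equal(group_fitness_two_goods(rep(0.5, 4), c1, c1, 1), 1)
  expect_equal(group_fitness_two_goods(c(1, 0, 1, 0), c1, c1, 1), 8 / 9)
  expect_error(group_fitness_two_goods(rep(0.5, 4), c1, diag(5), 1),
               "dimensions")
})
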