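test_that("birth-death sampling matches the Poisson stationary law", {
  # stationary distribution of (k, d) birth-death is Poisson(k/d):
  # mean k/d = 100, Fano factor 1.  Independent stationary draws (one per
  # ensemble cell, t >> 1/d) keep the moment estimates precise.
  net <- birth_death_net(k = 10, d = 0.1)
  ens <- gillespie_ensemble(net, 1e4, t_end = 100, frame_dt = 50, seed = 100,
                            obs_species = "X")
  x <- ens[, 3]
  expect_length(x, 1e4)
  expect_lt(abs(mean(x) - 100) / 100, 0.05)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("a network with no reactions keeps its initial counts", {
  net <- reaction_network(c("A", "B"), c(A = 3, B = 7), list())
  tr <- gillespie_run(net, t_end = 10, frame_dt = 0.5, seed = 1)
  expect_true(all(tr$counts["A", ] == 3))
  expect_true(all(tr$counts["B", ] == 7))
  expect_equal(ncol(tr$counts), 21)
})

test_that("pure decay matches the closed-form exponential mean", {
  d <- 0.2; n0 <- 200
  net <- decay_net(d, n0)
  ens <- gillespie_ensemble(net, 400, t_end = 10, frame_dt = 0.5, seed = 3,
                            obs_species = "X")
  for (tix in c(5, 11, 21)) {
    t <- (tix - 1) * 0.5
    expected <- n0 * exp(-d * t)
    se <- sqrt(n0 * exp(-d * t) * (1 - exp(-d * t)) / 400)
    expect_lt(abs(mean(ens[, tix]) - expected), 3 * se)
  }
})

test_that("ensembles are seed-reproducible and order-independent", {
  net <- birth_death_net()
  e1 <- gillespie_ensemble(net, 16, t_end = 50, frame_dt = 0.5, seed = 1,
                           obs_species = "X")
  e2 <- gillespie_ensemble(net, 16, t_end = 50, frame_dt = 0.5, seed = 1,
                           obs_species = "X")
  expect_identical(e1, e2)
  # cell i of a larger ensemble equals cell i of a smaller one (independent
  # counter-derived streams)
  e3 <- gillespie_ensemble(net, 4, t_end = 50, frame_dt = 0.5, seed = 1,
                           obs_species = "X")
  expect_identical(e1[1:4, ], e3[1:4, ])
  # singleton list equals gillespie_run with the derived stream
  one <- gillespie_ensemble(net, 1, t_end = 50, frame_dt = 0.5, seed = 9)
  expect_identical(one[[1]]$counts,
                   gillespie_run(net, 50, 0.5, seed = 9, stream = 1)$counts)
})

test_that("trajectory counts stay nonnegative integers for random networks", {
  set.seed(42)
  for (rep in 1:5) {
    net <- reaction_network(c("A", "B"), c(A = sample(0:20, 1), B = sample(0:20, 1)),
      list(reaction(prod = c(A = 1), rate = runif(1, 0, 20)),
           reaction(react = c(A = 1), prod = c(B = 1), rate = runif(1, 0, 1)),
           reaction(react = c(A = 1, B = 1), rate = runif(1, 0, 0.05)),
           reaction(react = c(B = 1), rate = runif(1, 0, 0.5))))
    tr <- gillespie_run(net, t_end = 100, frame_dt = 0.5, seed = rep)
    expect_true(all(tr$counts >= 0))
    expect_true(all(tr$counts == round(tr$counts)))
  }
})

test_that("doubling propensities and halving time leaves the law unchanged", {
  # time-rescaling property of the SSA: X(t) under rates r equals in
  # distribution X(t/2) under rates 2r
  n <- 2000
  slow <- gillespie_ensemble(birth_death_net(k = 5, d = 0.05), n,
                             t_end = 20, frame_dt = 20, seed = 4,
                             obs_species = "X")[, 2]
  fast <- gillespie_ensemble(birth_death_net(k = 10, d = 0.1), n,
                             t_end = 10, frame_dt = 10, seed = 5,
                             obs_species = "X")[, 2]
  ks <- suppressWarnings(stats::ks.test(slow, fast))
  expect_gt(ks$p.value, 0.01)
})

test_that("a frozen state is carried to the end when propensity hits zero", {
  net <- decay_net(d = 5, n0 = 3)
  tr <- gillespie_run(net, t_end = 50, frame_dt = 0.5, seed = 2)
  expect_equal(unname(tr$counts["X", ncol(tr$counts)]), 0)
  expect_equal(length(tr$frame_times), 101)
})
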