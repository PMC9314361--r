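test_that("a pure-death path makes exactly x0 jumps and is padded to the horizon", {
  pd <- reaction_network("X", list(reaction(1, 0, mass_action(1))),
                         output = "X", state0 = 5)
  tr <- ssa_simulate(pd, 100, seed = 2)
  expect_equal(length(tr$times) - 1L, 5L)
  expect_equal(unname(tr$states[nrow(tr$states), 1]), 0)
  expect_equal(time_average(tr, function(s) s[1], 50, 100), 0)
})

test_that("identical seeds give identical trajectories", {
  ge <- gene_expression()
  t1 <- ssa_simulate(ge, 50, seed = 99)
  t2 <- ssa_simulate(ge, 50, seed = 99)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
})

test_that("time averages are exact path integrals, invariant to event-grid refinement", {
  # hand-built two-segment path: state 2 on [0,1), state 4 on [1,2)
  tr <- structure(list(times = c(0, 1), states = matrix(c(2, 4), ncol = 1),
                       Tf = 2, network = birth_death()),
                  class = "ctmc_trajectory")
  expect_equal(time_average(tr, function(s) s[1], 0, 2), 3)
  # refining the grid with zero-displacement epochs changes nothing
  tr2 <- structure(list(times = c(0, 0.4, 1, 1.7),
                        states = matrix(c(2, 2, 4, 4), ncol = 1),
                        Tf = 2, network = birth_death()),
                   class = "ctmc_trajectory")
  expect_equal(time_average(tr2, function(s) s[1]^2, 0, 2),
               time_average(tr, function(s) s[1]^2, 0, 2))
  expect_error(time_average(tr, function(s) s[1], 2, 2), "empty")
})

test_that("birth-death is Poisson at stationarity: mean equals variance", {
  ens <- ssa_ensemble(birth_death(k = 1, gamma = 1), Q = 10, Tf = 1e4,
                      Tc = 100, seed = 5)
  mv <- stationary_mean_variance(ens)
  expect_within_3se(mv$mean, mv$mean_se, 1, "mean")
  pooled_se <- sqrt(mv$mean_se^2 + mv$variance_se^2)
  expect_lt(abs(mv$mean - mv$variance), 3 * pooled_se)
  # second moment E[X^2] = 2 via an exact path functional
  tr <- ssa_simulate(birth_death(), 1e4, seed = 8)
  m2 <- time_average(tr, function(s) s[1]^2, 100, 1e4)
  expect_lt(abs(m2 - 2), 0.2)
})

test_that("gene expression reaches the Lyapunov mean and variance", {
  ens <- ssa_ensemble(gene_expression(), Q = 10, Tf = 5e3, Tc = 100, seed = 3)
  mv <- stationary_mean_variance(ens)
  expect_within_3se(mv$mean, mv$mean_se, 40, "protein mean")
  expect_within_3se(mv$variance, mv$variance_se, 280 / 3, "protein variance")
})

test_that("the telegraph gene is active a fraction k_on/(k_on+k_off) of the time", {
  tr <- ssa_simulate(telegraph(k_on = 1, k_off = 3), 5e3, seed = 3)
  frac <- time_average(tr, function(s) s[1], 100, 5e3)
  expect_lt(abs(frac - 0.25), 0.03)
})

test_that("division completes a cell cycle in N/alpha time units on average", {
  cc <- cell_cycle_host(N = 4, alpha = 1)
  tr <- ssa_simulate(cc, 800, seed = 2)
  div <- which(vapply(cc$reactions,
                      function(r) identical(r$name, "division"), TRUE))
  cycles <- diff(tr$times[which(tr$which == div)])
  expect_gt(length(cycles), 100)
  expect_lt(abs(mean(cycles) - 4), 3 * sd(cycles) / sqrt(length(cycles)) + 0.2)
})

test_that("trajectories round-trip through CSV with their path functionals intact", {
  tr <- ssa_simulate(gene_expression(), 20, seed = 11)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_trajectory_csv(tr, tmp)
  back <- read_trajectory_csv(tmp, gene_expression())
  expect_equal(back$states[-nrow(back$states), ], tr$states)
  expect_equal(time_average(back, function(s) s[2], 5, 20),
               time_average(tr, function(s) s[2], 5, 20))
})

test_that("ensembles expose per-trajectory batches and within-path batching at Q = 1", {
  ens1 <- ssa_ensemble(birth_death(), Q = 1, Tf = 2000, Tc = 100, seed = 4,
                       n_batch = 20)
  mv <- stationary_mean_variance(ens1)
  expect_equal(length(mv$batch_mean), 20L)
  expect_false(is.na(mv$variance_se))
  ens <- ssa_ensemble(birth_death(), Q = 4, Tf = 2000, Tc = 100, seed = 4)
  expect_equal(length(stationary_mean_variance(ens)$batch_mean), 4L)
})
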