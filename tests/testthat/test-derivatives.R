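# The four Monte Carlo estimators (finite-point, naive-infinity,
# covariate-infinity, direct resolvent) against the truncated-generator
# oracle and the known closed forms.

test_that("all four estimators converge to the truncated-generator oracle", {
  orc_bd <- spectral_oracle(birth_death(k = 1, gamma = 1), bd_states(30))
  orc_tg <- spectral_oracle(telegraph(), telegraph_states())

  run <- function(net) pade_derivatives(net, s = c(1, Inf), rho = c(2, 3),
                                        s_test = c(1, 3), Q = 10, Tf = 5000,
                                        Tc = 100, seed = 2)
  for (case in list(list(net = birth_death(), orc = orc_bd),
                    list(net = telegraph(), orc = orc_tg))) {
    dv <- run(case$net)
    orc <- case$orc
    for (m in 0:1)
      expect_within_3se(dv$points[[1]]$D[m + 1], dv$points[[1]]$se[m + 1],
                        orc$D_fin(1, m), paste("finite m =", m))
    for (m in 0:2)
      expect_within_3se(dv$points[[2]]$D[m + 1], dv$points[[2]]$se[m + 1],
                        orc$D_inf(m), paste("infinity m =", m))
    for (r in 1:2)
      expect_within_3se(dv$direct$G[r], dv$direct$se[r],
                        orc$G(dv$direct$s[r]), paste("direct r =", r))
  }
})

test_that("the naive infinity estimator agrees with the oracle too", {
  orc <- spectral_oracle(birth_death(), bd_states(30))
  aug <- augment(birth_death(), test_points = 1)
  ens <- ssa_ensemble(aug, Q = 10, Tf = 5000, Tc = 100, seed = 2,
                      record_table = TRUE)
  nv <- infinity_derivatives_naive(ens, 4)
  for (m in 0:3)
    expect_within_3se(nv$D[m + 1], nv$se[m + 1], orc$D_inf(m),
                      paste("naive m =", m))
  # m = 0 is by construction the pooled variance estimator
  mv <- stationary_mean_variance(ens)
  expect_identical(nv$D[1], mv$variance)
})

test_that("birth-death derivatives match the resolvent closed form 1/(s+gamma)", {
  # G(s) = Var/(s+gamma) => D_m^(s) = (-1)^m Var/(s+gamma)^(m+1)
  dv <- pade_derivatives(birth_death(), s = 1, rho = 2, s_test = c(1, 3),
                         Q = 10, Tf = 1e4, Tc = 100, seed = 1)
  p <- dv$points[[1]]
  expect_within_3se(p$D[1], p$se[1], 0.5, "D0")
  expect_within_3se(p$D[2], p$se[2], -0.25, "D1")
  expect_within_3se(dv$direct$G[1], dv$direct$se[1], 0.5, "G(1)")
  expect_within_3se(dv$direct$G[2], dv$direct$se[2], 0.25, "G(3)")
  # register gaps are non-negative, so D_0^(s) <= Var/s
  expect_true(all(p$delta >= 0))
  expect_lte(p$D[1], dv$variance / 1 + 3 * p$se[1])
})

test_that("the covariate estimator is unbiased and beats the naive one at low order", {
  aug <- augment(gene_expression())
  ens <- ssa_ensemble(aug, Q = 10, Tf = 1e4, Tc = 100, seed = 1,
                      record_table = TRUE)
  cv <- infinity_derivatives_covariate(ens, 4)
  nv <- infinity_derivatives_naive(ens, 4)
  # exact generator moments from the linear theory: e_n' A^m Sigma e_n
  lin <- linearize(gene_expression())
  truth <- linear_derivatives(lin, Inf, 4)$points[[1]]$D
  for (m in 1:3)
    expect_within_3se(cv$D[m + 1], cv$se[m + 1], truth[m + 1],
                      paste("covariate m =", m))
  # variance reduction of the covariate integrand (m = 1, 2)
  for (m in 1:2) expect_lt(cv$se[m + 1], nv$se[m + 1])
  # D_0 from the covariate route is the pooled variance (stationarity check)
  expect_within_3se(cv$D[1], cv$se[1], truth[1], "D0 vs Lyapunov variance")
})

test_that("a frozen output gives zero gaps and zero direct estimates", {
  frozen <- reaction_network("X", list(reaction(8, 0, mass_action(1))),
                             output = "X", state0 = 7)
  dv <- pade_derivatives(frozen, s = 1, rho = 1, s_test = 2,
                         Q = 2, Tf = 200, Tc = 10, seed = 1)
  expect_equal(dv$points[[1]]$D[1], 0)
  expect_equal(dv$direct$G[1], 0)
  expect_equal(dv$variance, 0)
})

test_that("estimators demand the registers they rely on", {
  ens <- ssa_ensemble(augment(birth_death(), s_points = 1, rho = 2),
                      Q = 2, Tf = 200, Tc = 10, seed = 1)
  expect_error(finite_point_derivatives(ens, 2), "registers")
  expect_error(direct_G_estimates(ens), "Z registers")
})
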