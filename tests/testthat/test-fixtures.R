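test_that("every catalog network is constructible and simulatable", {
  for (name in list_fixtures()) {
    net <- make_network(name)
    expect_s3_class(net, "reaction_network")
    tr <- ssa_simulate(net, 5, seed = 1)
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(tr$states[, seq_len(net$d)] >= 0))
  }
  expect_error(make_network("no_such_network"), "available")
})

test_that("network configs round-trip through YAML field for field", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  for (name in c("nfb", "rna_splicing", "self_regulating_gene",
                 "cell_cycle_host")) {
    net <- make_network(name)
    write_network_yaml(net, tmp)
    back <- read_network_yaml(tmp)
    expect_equal(back$species, net$species)
    expect_equal(back$output, net$output)
    expect_equal(back$state0, net$state0)
    expect_equal(length(back$reactions), length(net$reactions))
    for (k in seq_along(net$reactions)) {
      r0 <- net$reactions[[k]]; r1 <- back$reactions[[k]]
      expect_equal(r1$reactants, r0$reactants)
      expect_equal(r1$displacement, r0$displacement)
      expect_equal(r1$propensity[names(r1$propensity) != "fn"],
                   r0$propensity[names(r0$propensity) != "fn"])
      expect_equal(is.null(r1$kernel), is.null(r0$kernel))
      if (!is.null(r0$kernel)) {
        expect_equal(r1$kernel$kind, r0$kernel$kind)
        expect_equal(r1$kernel$partition_species, r0$kernel$partition_species)
      }
    }
    # the round-tripped network produces the identical trajectory
    expect_identical(ssa_simulate(net, 3, seed = 5)$states,
                     ssa_simulate(back, 3, seed = 5)$states)
  }
})

test_that("the antithetic controller holds its set-point and feedback lowers variance", {
  mvs <- list()
  for (cfg in list(list(fb = "none", k = 0), list(fb = "hill", k = 0.25))) {
    net <- aif_gene_expression(k_fb = cfg$k, feedback = cfg$fb)
    ens <- ssa_ensemble(net, Q = 6, Tf = 3000, Tc = 200, seed = 2)
    mv <- stationary_mean_variance(ens)
    expect_within_3se(mv$mean, mv$mean_se, 40,
                      paste("set-point with", cfg$fb))
    mvs[[cfg$fb]] <- mv
  }
  expect_lt(mvs$hill$variance, mvs$none$variance)
})

test_that("the repressilator oscillates with and without the sponge plasmid", {
  for (sp in c(FALSE, TRUE)) {
    fit <- pade_psd(repressilator(H = 1.5, sponge = sp), p = 3,
                    s = c(0.5, 1, Inf), rho = c(2, 2, 3),
                    s_test = c(0.3, 0.7, 1.5), Q = 8, Tf = 3000, Tc = 100,
                    seed = 1)
    expect_true(attr(fit$validation, "pass"))
    expect_gt(peak_frequency(fit$rational), 0.3)
  }
})

test_that("cooperativity reshapes the normalised spectrum detectably", {
  grid <- seq(0.05, 3, length.out = 60)
  curves <- lapply(c(1, 3), function(H) {
    fit <- pade_psd(self_regulating_gene(H = H), p = 2, s = Inf, rho = 4,
                    s_test = c(0.5, 1, 2), Q = 10, Tf = 5000, Tc = 100,
                    seed = 2)
    normalized_psd_curve(fit$rational, grid)$npsd
  })
  # band: standard error of the 100-trace averaged normalised periodogram,
  # the precision of the inference study's experimental reference
  Q <- 100
  tr <- synthetic_experiment_traces(self_regulating_gene(H = 1), Q = Q,
                                    dt = 0.05, Tf = 1000, Tc = 100, seed = 3)
  pgs <- vapply(seq_len(Q), function(q) {
    pg <- periodogram(tr$values[, q], dt = tr$dt)
    v <- approx(pg$omega, pg$psd, grid)$y
    a <- sum(diff(grid) * (v[-1] + v[-length(v)]) / 2)
    v / a
  }, numeric(length(grid)))
  band <- mean(apply(pgs, 1, sd)) / sqrt(Q)
  expect_gt(max(abs(curves[[1]] - curves[[2]])), 5 * band)
})

test_that("normalised spectra are invariant to the proportionality constant", {
  n1 <- normalized_psd(synthetic_experiment_traces(
    self_regulating_gene(), Q = 4, dt = 0.1, scale = 1,
    Tf = 500, Tc = 50, seed = 9))
  n2 <- normalized_psd(synthetic_experiment_traces(
    self_regulating_gene(), Q = 4, dt = 0.1, scale = 7.3,
    Tf = 500, Tc = 50, seed = 9))
  expect_equal(n1$npsd, n2$npsd, tolerance = 1e-10)
  expect_error(synthetic_experiment_traces(self_regulating_gene(), Q = 0),
               "Q")
  expect_error(synthetic_experiment_traces(self_regulating_gene(),
                                           scale = -1), "scale")
})

test_that("spectral inference recovers the true cooperativity from scaled traces", {
  norm_on <- function(om, v) {
    v / sum(diff(om) * (v[-1] + v[-length(v)]) / 2)
  }
  tgt <- synthetic_experiment_traces(self_regulating_gene(H = 1), Q = 100,
                                     dt = 0.05, scale = 7.3, Tf = 2000,
                                     Tc = 100, seed = 5)
  ref <- normalized_psd(tgt)
  grid <- seq(0.05, 3, 0.05)
  refv <- norm_on(grid, approx(ref$omega, ref$npsd, grid)$y)
  Hs <- c(0.5, 1, 2, 3)
  d2 <- vapply(Hs, function(H) {
    fit <- pade_psd(self_regulating_gene(H = H), p = 2, s = Inf, rho = 4,
                    s_test = c(0.5, 1, 2), Q = 10, Tf = 5000, Tc = 100,
                    seed = 2)
    pv <- norm_on(grid, pmax(psd_eval(fit$rational, grid), 0))
    sqrt(mean((pv - refv)^2))
  }, numeric(1))
  expect_equal(Hs[which.min(d2)], 1)
})
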