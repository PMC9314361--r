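test_that("interpolation blocks carry the printed binomial/power structure", {
  d <- c(0.7, -0.3)
  # finite point, p = 2, s = 2: rows derived by hand from the
  # numerator-minus-G-times-denominator order matching
  blk <- pade_block(2, d, p = 2)
  expect_equal(blk$A[1, ], c(1, 2, -d[1], -2 * d[1]))
  expect_equal(blk$A[2, ], c(0, 1, -d[2], -(2 * d[2] + d[1])))
  expect_equal(blk$b, c(4 * d[1], 4 * d[2] + 4 * d[1]))
  # infinity point, p = 1, rho = 2: kappa0 = D0 and -D0 beta0 = D1
  bi <- pade_block(Inf, d, p = 1)
  expect_equal(bi$A, rbind(c(1, 0), c(0, -d[1])))
  expect_equal(bi$b, d)
  # infinity point: row j = 0 has a single 1 at column p - 1
  b3 <- pade_block(Inf, 0.5, p = 3)
  expect_equal(b3$A[1, ], c(0, 0, 1, 0, 0, 0))
  expect_error(pade_block(Inf, d, p = 0), "p must be")
})

test_that("exact birth-death derivatives give the exact Cauchy spectrum", {
  lin <- linearize(birth_death(k = 1, gamma = 1))
  r <- pade_solve(linear_derivatives(lin, Inf, 4), p = 1)
  expect_equal(r$kappa, 1, tolerance = 1e-12)
  expect_equal(r$den, c(1, 1), tolerance = 1e-12)
  expect_equal(psd_eval(r, 0), 2, tolerance = 1e-12)   # 2k/gamma^2
  expect_equal(psd_eval(r, 1), 1, tolerance = 1e-12)   # 2/(1+1)
  expect_true(r$stable)
})

test_that("oracle-exact recovery holds to 8+ digits with p = number of modes", {
  # telegraph: a single significant mode
  tg <- linearize(telegraph())
  rt <- pade_solve(linear_derivatives(tg, Inf, 4), p = 1)
  s_pts <- c(0.3, 0.7, 1.3, 2.2, 3.7, 5, 7.7, 11, 17, 29)
  expect_lt(max(abs(G_eval(rt, s_pts) - linear_G(tg, s_pts)) /
                  abs(linear_G(tg, s_pts))), 1e-8)
  expect_equal(psd_eval(rt, 0), 0.09375, tolerance = 1e-10)
  # truncated birth-death oracle (cap 30), all four derivative routes exact
  orc <- spectral_oracle(birth_death(), bd_states(30))
  derivs <- list(points = list(list(s = Inf, D = sapply(0:3, orc$D_inf))))
  rb <- pade_solve(derivs, p = 1)
  expect_lt(max(abs(G_eval(rb, s_pts) - orc$G(s_pts)) / abs(orc$G(s_pts))),
            1e-8)
})

test_that("multipoint interpolation recovers the three-mode splicing spectrum", {
  lin <- linearize(rna_splicing())
  dv <- linear_derivatives(lin, c(1, 1.5, 2, Inf), c(2, 2, 2, 3))
  r <- pade_solve(dv, p = 3)
  pr <- psd_polynomial(r)
  expect_equal(pr$num_u, c(219.84, 30, 1.2), tolerance = 1e-8)
  expect_equal(pr$den_u, c(36, 150.25, 25.25, 1), tolerance = 1e-8)
})

test_that("a known denominator factor restricts the ansatz consistently", {
  lin <- linearize(rna_splicing())
  dv <- linear_derivatives(lin, c(1, 1.5, 2, Inf), c(2, 2, 2, 3))
  free <- pade_solve(dv, p = 3)
  # q = 0 reduces to the unconstrained system bit for bit
  q0 <- pade_solve(dv, p = 3, known_factor = numeric(0))
  expect_identical(q0$den, free$den)
  expect_identical(q0$kappa, free$kappa)
  # supplying a true factor (s+3)(s+4) = 12 + 7s + s^2 recovers the rest
  kf <- pade_solve(dv, p = 3, known_factor = c(12, 7))
  expect_equal(kf$beta_free, 0.5, tolerance = 1e-8)
  expect_equal(kf$den, free$den, tolerance = 1e-8)
  expect_error(pade_solve(dv, p = 1, known_factor = c(12, 7)), "exceeds p")
})

test_that("cell-cycle clocks contribute the documented quadratic factor", {
  expect_equal(known_factor_cell_cycle(4, 1), c(2, 2))
  expect_equal(known_factor_cell_cycle(2, 1), c(4, 4))
  # coefficients scale as (alpha^2, alpha)
  b1 <- known_factor_cell_cycle(6, 1)
  b3 <- known_factor_cell_cycle(6, 3)
  expect_equal(b3, c(9 * b1[1], 3 * b1[2]))
  expect_error(known_factor_cell_cycle(1, 1), "N must be")
})

test_that("validation flags accurate and under-ordered approximants", {
  lin <- linearize(rna_splicing())
  dv <- linear_derivatives(lin, c(1, 1.5, 2, Inf), c(2, 2, 2, 3))
  # test points spanning well beyond the interpolation points, so that a
  # missing slow/fast mode is visible
  sbar <- c(0.1, 0.3, 6)
  direct <- list(s = sbar, G = linear_G(lin, sbar), se = rep(1e-9, 3))
  good <- validate_pade(pade_solve(dv, p = 3), direct)
  expect_true(attr(good, "pass"))
  expect_lt(max(good$rel_err), 1e-8)
  # deliberately under-ordered p = 1 on a three-mode spectrum fails
  bad <- validate_pade(pade_solve(dv, p = 1), direct)
  expect_false(attr(bad, "pass"))
  expect_gt(max(bad$rel_err), 0.1)
})

test_that("the PSD evaluator reports raw and clipped values and flags poles", {
  r <- structure(list(kappa = 1, den = c(1, 0, 1), beta_free = c(1, 0),
                      B = numeric(0), p = 2, q = 0L,
                      roots = polyroot(c(1, 0, 1)), stable = FALSE),
                 class = "rational_psd")
  expect_true(is.infinite(psd_eval(r, 1)))  # denominator root at i*1
  expect_false(r$stable)
  v <- psd_eval(r, 2)   # 2*Re(1/(-3)) < 0
  expect_lt(v, 0)
  expect_equal(psd_eval(r, 2, clip = TRUE), 0)
})

test_that("peak detection separates oscillatory from monotone spectra", {
  expect_equal(peak_frequency(linearize(iff_network())), 0)
  expect_equal(peak_frequency(linearize(nfb_network())), 0.8211,
               tolerance = 1e-3)
  cauchy <- function(om) 2 / (1 + om^2)
  expect_equal(peak_frequency(cauchy, omega_hi = 10), 0)
})

test_that("the entrainment score integrates band power over total power", {
  cauchy <- function(om) 2 / (1 + om^2)
  expect_equal(entrainment_score(cauchy, 1),
               2 / pi * (atan(1.1) - atan(0.9)), tolerance = 1e-6)
  expect_equal(entrainment_score(cauchy, 1, band = c(1, 1)), 0)
  # a spectrum concentrated in the band scores near 1
  sharp <- function(om) stats::dnorm(om, 1, 0.01)
  expect_gt(entrainment_score(sharp, 1), 0.99)
  expect_error(entrainment_score(function(om) rep(1, length(om)), 1))
})
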