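test_that("linearize extracts the affine structure and Lyapunov covariance", {
  lin <- linearize(gene_expression())
  expect_equal(lin$A, rbind(c(-1, 0), c(2, -0.5)))
  expect_equal(lin$xbar, c(10, 40))
  expect_equal(lin$Sigma, rbind(c(10, 40 / 3), c(40 / 3, 280 / 3)),
               tolerance = 1e-10)
  bd <- linearize(birth_death(k = 3, gamma = 1.5))
  expect_equal(as.numeric(bd$A), -1.5)
  expect_equal(as.numeric(bd$Sigma), 2)  # Poisson(k/gamma)
  tg <- linearize(telegraph())
  expect_equal(tg$xbar, 0.25)
})

test_that("the Lyapunov residual vanishes for every linear fixture", {
  for (name in c("birth_death", "telegraph", "gene_expression",
                 "rna_splicing", "iff", "nfb", "feedback_gene_expression")) {
    lin <- linearize(make_network(name))
    res <- lin$A %*% lin$Sigma + lin$Sigma %*% t(lin$A) + lin$DDt
    expect_lt(norm(res, "F"), 1e-10 * norm(lin$DDt, "F"))
    # exact spectrum is non-negative
    expect_true(all(psd_exact(lin, seq(0, 10, length.out = 50)) >= 0))
  }
})

test_that("non-affine or kernel-bearing networks are rejected by name", {
  expect_error(linearize(self_regulating_gene()), "non-affine")
  dimer <- reaction_network("X", list(
    reaction(2, 0, mass_action(1), name = "dimer_decay"),
    reaction(0, 1, mass_action(5))), output = "X")
  expect_error(linearize(dimer), "dimer_decay")
  expect_error(linearize(cell_cycle_host()), "kernel")
  pure_birth <- reaction_network("X", list(reaction(0, 1, mass_action(1))),
                                 output = "X")
  expect_error(linearize(pure_birth), "Hurwitz")
})

test_that("every tabulated analytic PSD coefficient reproduces exactly", {
  pr <- psd_rational_exact(linearize(gene_expression()))
  expect_equal(pr$num_u, c(120, 40), tolerance = 1e-9)
  expect_equal(pr$den_u, c(0.25, 1.25, 1), tolerance = 1e-9)
  pr <- psd_rational_exact(linearize(iff_network()))
  expect_equal(pr$num_u, c(112, 94), tolerance = 1e-9)
  expect_equal(pr$den_u, c(0.25, 1.25, 1), tolerance = 1e-9)
  pr <- psd_rational_exact(linearize(nfb_network()))
  expect_equal(pr$num_u, c(200, 200 / 3), tolerance = 1e-9)
  expect_equal(pr$den_u, c(2.25, -0.75, 1), tolerance = 1e-9)
  pr <- psd_rational_exact(linearize(rna_splicing()))
  expect_equal(pr$num_u, c(219.84, 30, 1.2), tolerance = 1e-8)
  expect_equal(pr$den_u, c(36, 150.25, 25.25, 1), tolerance = 1e-8)
})

test_that("the spectral decomposition is additive for stimulated linear circuits", {
  om <- seq(0, 6, length.out = 40)
  # gene expression = protein birth-death driven by the mRNA spectrum
  ge <- linearize(gene_expression())
  prot <- reaction_network("protein", list(
    reaction(0, 1, mass_action(2 * 10), name = "translation_at_mean"),
    reaction(1, 0, mass_action(0.5))), output = "protein")
  mrna_psd <- function(w) 2 * 10 / (1 + w^2)
  dec <- psd_decompose(linearize(prot),
                       input_signal(2, 1, mrna_psd, 10), om)
  expect_equal(dec$total, psd_exact(ge, om), tolerance = 1e-8)
  # the two terms are the tabulated translation/transcription components
  expect_equal(dec$intrinsic, 40 / (0.25 + om^2), tolerance = 1e-8)
  expect_equal(dec$extrinsic_1, 80 / ((0.25 + om^2) * (1 + om^2)),
               tolerance = 1e-8)
  # RNA splicing = U/S cascade driven by the telegraph spectrum
  sp <- linearize(rna_splicing())
  ds <- reaction_network(c("U", "S"), list(
    reaction(c(0, 0), c(1, 0), mass_action(1.8), name = "transcription_at_mean"),
    reaction(c(1, 0), c(0, 1), mass_action(1)),
    reaction(c(1, 0), c(0, 0), mass_action(2)),
    reaction(c(0, 1), c(0, 0), mass_action(0.5))), output = "S")
  tg_psd <- function(w) 2 * 3 / (4 * (16 + w^2))
  dec2 <- psd_decompose(linearize(ds),
                        input_signal(5.6, c(1, 0), tg_psd, 0.25), om)
  expect_equal(dec2$total, psd_exact(sp, om), tolerance = 1e-8)
  # a zero-strength input contributes nothing
  dec0 <- psd_decompose(linearize(ds),
                        input_signal(1e-12, c(1, 0), tg_psd, 0.25), om)
  expect_lt(max(dec0$extrinsic_1), 1e-12)
})

test_that("total signal power equals the stationary output variance", {
  for (name in c("birth_death", "gene_expression", "rna_splicing", "nfb")) {
    lin <- linearize(make_network(name))
    f <- function(om) psd_exact(lin, om)
    pw <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value / pi
    expect_equal(pw, lin$Sigma[lin$output, lin$output], tolerance = 1e-6)
  }
})

test_that("the feedforward spectrum is monotone, the feedback criterion sharp", {
  iff <- linearize(iff_network())
  om <- seq(0, 10, length.out = 400)
  expect_true(all(diff(psd_exact(iff, om)) < 0))
  # printed example: threshold ~0.4687, drive = 1 -> oscillatory
  expect_true(nfb_oscillation_criterion(1, 0.5, 2, 0.05, 10))
  expect_false(nfb_oscillation_criterion(1, 0.5, 2, 0.05, 1e-9))
  # boundary equality is not oscillation (strict inequality)
  thr_drive <- function(gc, go, ko) {
    Gam <- (gc * go + gc^2 + ko * gc)^2 + gc^4 + gc^3 * ko + go^2 * gc * ko
    (gc^4 + gc^3 * ko + go^2 * gc * ko) / (sqrt(Gam) + gc * go + gc^2 + ko * gc)
  }
  b_eq <- thr_drive(1, 0.5, 2) / (2 * 10)
  expect_false(nfb_oscillation_criterion(1, 0.5, 2, b_eq, 10))
})

test_that("the oscillation criterion agrees with the analytic peak on a grid", {
  betas <- seq(0.005, 0.09, length.out = 10)
  I0s <- seq(1, 30, length.out = 10)
  for (b in betas) for (I0 in I0s) {
    crit <- nfb_oscillation_criterion(1, 0.5, 2, b, I0)
    lin <- linearize(nfb_network(I0 = I0, beta_fb = b))
    peak <- peak_frequency(lin)
    expect_identical(crit, peak > 0,
                     label = paste("beta_fb =", b, "I0 =", I0))
  }
})

test_that("composite spectra reduce to the isolated circuit at zero coupling", {
  om <- seq(0, 4, length.out = 30)
  lin <- linearize(feedback_gene_expression())
  up_psd <- function(w) 6 / (1 + (w - 1.4)^2 * 25)
  comp <- composite_psd(lin, input_signal(1e-12, c(1, 0), up_psd, 8), om)
  expect_equal(comp$total, psd_exact(lin, om), tolerance = 1e-8)
  # stronger coupling adds strictly more power at the driver frequency
  c1 <- composite_psd(linearize(feedback_gene_expression(input_const = 0.5 * 8)),
                      input_signal(0.5, c(1, 0), up_psd, 8), om)
  expect_true(all(c1$total >= psd_exact(linearize(
    feedback_gene_expression(input_const = 0.5 * 8)), om)))
})
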