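test_that("mass-action propensities follow the combinatorial rate law", {
  # zeroth order: constant
  r <- reaction(c(0, 0), c(1, 0), mass_action(10))
  expect_equal(propensity(r, c(3, 7)), 10)
  # first order
  r <- reaction(c(0, 1), c(0, 0), mass_action(0.5))
  expect_equal(propensity(r, c(3, 7)), 3.5)
  # bimolecular homodimer: theta * x(x-1)/2
  r <- reaction(c(2, 0), c(0, 0), mass_action(1))
  expect_equal(propensity(r, c(3, 0)), 3)
  # insufficient reactants: exactly zero
  for (x in list(c(1, 0), c(0, 5), c(1, 1))) {
    expect_equal(propensity(reaction(c(2, 1), c(0, 0), mass_action(4)), x), 0)
  }
  expect_error(propensity(r, c(-1, 0)), "non-negative")
})

test_that("custom and structured propensities clamp at zero", {
  r <- reaction(c(0), c(1), custom_propensity(function(x) 5 - x[1]))
  expect_equal(propensity(r, 2), 3)
  expect_equal(propensity(r, 9), 0)
  ra <- reaction(c(0, 0), c(1, 0), affine_propensity(5, c(0, -1)))
  expect_equal(propensity(ra, c(0, 9)), 0)
})

test_that("the generator matches explicit enumeration and kills constants", {
  set.seed(42)
  for (net in list(gene_expression(), nfb_network(), rna_splicing())) {
    for (rep in 1:5) {
      x <- rpois(net$d, 8)
      h <- function(s) s[1]^2 + 3 * s[net$d] - 2
      manual <- 0
      for (r in net$reactions) {
        manual <- manual +
          propensity(r, x) * (h(x + r$displacement) - h(x))
      }
      expect_equal(apply_generator(net, h, x), manual)
      expect_equal(apply_generator(net, function(s) 4.2, x), 0)
    }
  }
})

test_that("generator powers of the output function have the known closed forms", {
  bd <- birth_death(k = 1, gamma = 1)
  for (x in c(0, 1, 5, 12)) {
    # A f = k - gamma x = -(x - 1); A^m f = (-gamma)^m f
    expect_equal(generator_power(bd, 1, x, center = 1), -(x - 1))
    expect_equal(generator_power(bd, 2, x, center = 1), (x - 1))
    expect_equal(generator_power(bd, 0, x, center = 1), x - 1)
  }
  ge <- gene_expression()
  expect_equal(generator_power(ge, 1, c(10, 40), center = 40), 0)
})

test_that("the generator maps affine functions to affine functions on linear networks", {
  # oracle: A^m f(x) = e_n' A^m (x - xbar) from the linear matrices
  for (name in c("gene_expression", "rna_splicing", "telegraph")) {
    net <- make_network(name)
    lin <- linearize(net)
    n <- net$output
    # probe at states actually visited by the chain, so that clamped
    # affine rates stay in their linear regime
    tr <- ssa_simulate(net, 20, seed = 7)
    probes <- unique(tr$states[, seq_len(net$d), drop = FALSE])
    probes <- probes[seq_len(min(4, nrow(probes))), , drop = FALSE]
    for (rep in seq_len(nrow(probes))) {
      x <- probes[rep, ]
      for (m in 0:3) {
        Am <- diag(net$d)
        if (m > 0) for (i in seq_len(m)) Am <- Am %*% lin$A
        expect_equal(generator_power(net, m, x, center = lin$xbar[n]),
                     as.numeric(Am[n, ] %*% (x - lin$xbar)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("partition kernels expose correct conditional moments", {
  kb <- binomial_partition_kernel(1:2)
  expect_equal(kernel_mean(kb, c(6, 9)), c(3, 4.5))
  expect_equal(kernel_cov_diag(kb, c(6, 9)), c(1.5, 2.25))
  ks <- strict_binary_kernel(1:2)
  expect_equal(kernel_mean(ks, c(6, 9)), c(3, 4.5))
  expect_equal(kernel_cov_diag(ks, c(6, 9)), c(0, 0.25))
  # sampled strict-binary post-state within 1 of half, binomial non-negative
  set.seed(1)
  for (rep in 1:50) {
    x <- c(rpois(1, 10), rpois(1, 7))
    xs <- ctmcpsd:::sample_kernel(ks, x)
    expect_true(all(abs(xs - x / 2) <= 0.5 + 1e-12))
    xb <- ctmcpsd:::sample_kernel(kb, x)
    expect_true(all(xb >= 0 & xb <= x))
  }
})

test_that("partition reactions enter the generator through kernel means", {
  # constant-rate binomial partition of the output: A x_n = alpha (x_n/2 - x_n)
  net <- reaction_network(
    species = "X",
    reactions = list(
      reaction(0, 1, mass_action(2)),
      reaction(0, propensity = mass_action(0.3),
               kernel = binomial_partition_kernel(1))),
    output = "X", state0 = 6)
  a <- 0.3
  expect_equal(apply_generator(net, function(s) s[1], 6), 2 + a * (3 - 6))
  # non-affine h with a kernel is unsupported
  expect_error(apply_generator(net, function(s) s[1]^2, 6), "affine")
})
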