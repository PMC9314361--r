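#' Apply the CTMC generator to a function
#'
#' Computes \eqn{\mathbb{A}h(x) = \sum_k \lambda_k(x)\,
#' E_{\mu_k}[h(x + \zeta) - h(x)]}.  For fixed-displacement reactions the
#' expectation is the plain difference \eqn{h(x+\zeta_k) - h(x)}; for
#' reactions with a random jump kernel the expectation is taken under the
#' kernel, which requires `h` to be affine (verified by probing) so that the
#' kernel's closed-form conditional mean suffices.
#'
#' @param network A [reaction_network()].
#' @param h Function `state -> numeric(1)`, finite at the state and its
#'   one-jump neighbours.
#' @param state Non-negative integer state vector.
#' @return \eqn{\mathbb{A}h(x)}.
#' @export
apply_generator <- function(network, h, state) {
  if (any(state < 0)) stop("state must be componentwise non-negative")
  d <- network$d
  aff <- NULL  # lazily computed affine representation of h
  total <- 0
  for (r in network$reactions) {
    lam <- propensity(r, state)
    if (lam == 0) next
    if (is.null(r$kernel)) {
      total <- total + lam * (h(state + r$displacement) - h(state))
    } else {
      if (is.null(aff)) {
        aff <- affine_rep(h, d)
        if (is.null(aff))
          stop("generator with a random jump kernel requires an affine ",
               "function (kernel moment interface covers first moments only)")
      }
      mu <- kernel_mean(r$kernel, state)
      total <- total + lam * sum(aff$a * (mu - state))
    }
  }
  total
}

# Probe h for an affine representation h(x) = c + a.x on the non-negative
# lattice; returns list(a, c) or NULL if the probes are inconsistent.
affine_rep <- function(h, d, tol = 1e-8) {
  zero <- rep(0, d)
  c0 <- h(zero)
  a <- numeric(d)
  for (j in seq_len(d)) {
    ej <- zero; ej[j] <- 1
    a[j] <- h(ej) - c0
    e2 <- zero; e2[j] <- 2
    if (abs(h(e2) - (c0 + 2 * a[j])) >
        tol * (1 + abs(c0) + abs(a[j]))) return(NULL)
  }
  for (probe in list(rep(3, d), seq_len(d), rev(seq_len(d)) * 2)) {
    if (abs(h(probe) - (c0 + sum(a * probe))) >
        tol * (1 + abs(c0) + sum(abs(a * probe)))) return(NULL)
  }
  list(a = a, c = c0)
}

#' Memoised evaluator of generator powers applied to the output function
#'
#' Returns a function `(m, state)` evaluating \eqn{\mathbb{A}^m f(x)} with
#' \eqn{f(x) = x_n - c}, where `n` is the network's output species and `c`
#' the (estimated) stationary mean.  Values are cached in a lookup table
#' keyed by `(m, state)`: ergodic chains revisit the same states constantly,
#' so the recursion cost is paid once per visited state.  The cache is
#' flushed when it exceeds `cache_cap` entries.
#'
#' Note that for `m >= 1` the value is independent of `c` (the generator
#' annihilates constants), so the centring only matters for `m = 0`.
#'
#' @param network A [reaction_network()].
#' @param center Centring constant `c` (stationary output mean).
#' @param cache_cap Maximum number of cached values.
#' @return Function `(m, state) -> numeric(1)`.
#' @export
generator_power_evaluator <- function(network, center = 0, cache_cap = 2e6) {
  n <- network$output
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  count <- 0L
  # affine representations of A^m f per level, for kernel reactions
  aff_levels <- list()

  eval_m <- function(m, state) {
    if (m == 0L) return(unname(state[n] - center))
    key <- paste0(m, "|", paste0(state, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    total <- 0
    for (r in network$reactions) {
      lam <- propensity(r, state)
      if (lam == 0) next
      if (is.null(r$kernel)) {
        total <- total + lam * (eval_m(m - 1L, state + r$displacement) -
                                  eval_m(m - 1L, state))
      } else {
        lev <- as.character(m - 1L)
        if (is.null(aff_levels[[lev]])) {
          aff <- affine_rep(function(x) eval_m(m - 1L, x), network$d)
          if (is.null(aff))
            stop("A^m f with random jump kernels is only supported while ",
                 "A^(m-1) f stays affine; use finite interpolation points ",
                 "for this network")
          aff_levels[[lev]] <<- aff
        }
        aff <- aff_levels[[lev]]
        mu <- kernel_mean(r$kernel, state)
        total <- total + lam * sum(aff$a * (mu - state))
      }
    }
    if (count > cache_cap) {
      rm(list = ls(cache, all.names = TRUE), envir = cache)
      count <<- 0L
    }
    cache[[key]] <- total
    count <<- count + 1L
    total
  }
  eval_m
}

#' Evaluate \eqn{\mathbb{A}^m f} at a state
#'
#' Convenience wrapper around [generator_power_evaluator()] for one-off
#' evaluations; `f(x) = x_n - center`.
#'
#' @inheritParams generator_power_evaluator
#' @param m Non-negative integer power; `m = 0` returns `f(state)`.
#' @param state Non-negative integer state vector.
#' @export
generator_power <- function(network, m, state, center = 0) {
  stopifnot(m >= 0, m == round(m))
  generator_power_evaluator(network, center)(as.integer(m), state)
}

# gamma_{jl}(x) = sum_k lambda_k(x) E_mu[(A^j f(x+z) - A^j f(x)) *
#                                        (A^l f(x+z) - A^l f(x))]
# For fixed displacements the expectation is a plain product; for partition
# kernels it uses the kernel's first/second conditional moments with the
# affine representation of A^j f (components independent).
gamma_jl <- function(network, j, l, state, amf) {
  total <- 0
  aff_j <- aff_l <- NULL
  for (r in network$reactions) {
    lam <- propensity(r, state)
    if (lam == 0) next
    if (is.null(r$kernel)) {
      xz <- state + r$displacement
      dj <- amf(j, xz) - amf(j, state)
      dl <- amf(l, xz) - amf(l, state)
      total <- total + lam * dj * dl
    } else {
      if (is.null(aff_j)) {
        aff_j <- affine_rep(function(x) amf(j, x), network$d)
        aff_l <- if (l == j) aff_j else
          affine_rep(function(x) amf(l, x), network$d)
        if (is.null(aff_j) || is.null(aff_l))
          stop("covariate gamma terms with jump kernels require affine A^m f")
      }
      mu <- kernel_mean(r$kernel, state)
      v <- kernel_cov_diag(r$kernel, state)
      mj <- sum(aff_j$a * (mu - state))
      ml <- sum(aff_l$a * (mu - state))
      total <- total + lam * (sum(aff_j$a * aff_l$a * v) + mj * ml)
    }
  }
  total
}

# Covariate integrand Psi_m(x) for the infinity-point Pade derivative,
# m >= 1; its stationary mean equals D_m^(inf) = E_pi[f A^m f] but with a
# much smaller Monte Carlo variance than the naive integrand.  Independent
# of the centring constant for all m >= 1.
psi_covariate <- function(network, m, state, amf) {
  stopifnot(m >= 1)
  r <- m %/% 2L
  acc <- 0
  if (m %% 2L == 0L) {
    acc <- acc + 0.5 * choose(m, r) * amf(r, state)^2
    if (r >= 2L) for (k in seq_len(r - 1L))
      acc <- acc + choose(m, k) * amf(k, state) * amf(m - k, state)
    for (k in seq_len(r) - 1L)
      acc <- acc + choose(m - 1L, k) * gamma_jl(network, k, m - 1L - k, state, amf)
  } else {
    if (r >= 1L) for (k in seq_len(r))
      acc <- acc + choose(m, k) * amf(k, state) * amf(m - k, state)
    if (r >= 1L) for (k in seq_len(r) - 1L)
      acc <- acc + choose(m - 1L, k) * gamma_jl(network, k, m - 1L - k, state, amf)
    acc <- acc + 0.5 * choose(m - 1L, r) * gamma_jl(network, r, r, state, amf)
  }
  -acc
}
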