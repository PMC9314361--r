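# Exact spectral machinery for linear (affine-propensity) networks: the
# propensity vector is lambda(x) = Lambda x + btilde, the mean obeys
# dx/dt = A x + b with A = S Lambda, b = S btilde, and the stationary
# covariance Sigma solves the Lyapunov equation
#   A Sigma + Sigma A' + D D' = 0,  D D' = S diag(Lambda xbar + btilde) S'.
# The output PSD is S(w) = -2 e_n' (w^2 I + A^2)^{-1} A Sigma e_n.

#' Extract the affine structure of a linear network
#'
#' Verifies that every propensity is affine in the state (zeroth- or
#' first-order mass action, constants, or affine rate laws; the clamp of a
#' clamped-affine rate is ignored here, which is exact as long as the
#' dynamics rarely visits the clamped region) and that all displacements
#' are fixed, then assembles the matrices of the linear theory and solves
#' the Lyapunov equation for the stationary covariance.
#'
#' @param network A [reaction_network()].
#' @return A `"linear_network"` with fields `Lambda`, `btilde`, `S`, `A`,
#'   `b`, `xbar`, `Sigma`, `DDt`, `output`.
#' @export
linearize <- function(network) {
  d <- network$d
  K <- length(network$reactions)
  Lambda <- matrix(0, K, d)
  btilde <- numeric(K)
  S <- matrix(0, d, K)
  for (k in seq_len(K)) {
    r <- network$reactions[[k]]
    if (!is.null(r$kernel))
      stop("reaction ", k, if (!is.null(r$name)) paste0(" (", r$name, ")"),
           " has a random jump kernel: not a linear network")
    p <- r$propensity
    ord <- sum(r$reactants)
    if (p$type == "mass_action") {
      if (ord == 0) btilde[k] <- p$rate
      else if (ord == 1) Lambda[k, which(r$reactants == 1)] <- p$rate
      else stop("reaction ", k,
                if (!is.null(r$name)) paste0(" (", r$name, ")"),
                " is not affine (mass-action order ", ord, ")")
    } else if (p$type == "const") {
      btilde[k] <- p$value
    } else if (p$type == "affine") {
      btilde[k] <- p$const
      Lambda[k, ] <- p$coef
    } else {
      stop("reaction ", k, if (!is.null(r$name)) paste0(" (", r$name, ")"),
           " has a non-affine propensity (", p$type, ")")
    }
    S[, k] <- r$displacement
  }
  A <- S %*% Lambda
  b <- as.numeric(S %*% btilde)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("A is not Hurwitz-stable: the linear network is not ergodic")
  xbar <- as.numeric(solve(A, -b))
  rates <- as.numeric(Lambda %*% xbar + btilde)
  DDt <- S %*% diag(rates, nrow = K) %*% t(S)
  Sigma <- lyapunov_solve(A, DDt)
  structure(list(Lambda = Lambda, btilde = btilde, S = S, A = A, b = b,
                 xbar = xbar, Sigma = Sigma, DDt = DDt,
                 output = network$output, species = network$species,
                 d = d),
            class = "linear_network")
}

# Solve A X + X A' + Q = 0 for symmetric X (dense, d moderate).
lyapunov_solve <- function(A, Q) {
  d <- nrow(A)
  I <- diag(d)
  M <- kronecker(I, A) + kronecker(A, I)
  X <- matrix(solve(M, -as.numeric(Q)), d, d)
  (X + t(X)) / 2
}

#' @export
print.linear_network <- function(x, ...) {
  cat("<linear_network> d = ", x$d, "; output ", x$species[x$output],
      "; xbar = (", paste(format(x$xbar, digits = 5), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Exact PSD of a linear network
#'
#' \eqn{S_{X_n}(\omega) = -2 e_n^T (\omega^2 I + A^2)^{-1} A \Sigma e_n}.
#'
#' @param lin A `"linear_network"` from [linearize()].
#' @param omega Frequency vector (rad / time unit).
#' @param output Optional output species override (index).
#' @export
psd_exact <- function(lin, omega, output = lin$output) {
  ASn <- (lin$A %*% lin$Sigma)[, output]
  I <- diag(lin$d)
  A2 <- lin$A %*% lin$A
  vapply(omega, function(w) {
    M <- w^2 * I + A2
    v <- tryCatch(solve(M, ASn), error = function(e) {
      warning("near-singular resolvent at omega = ", w,
              "; using a perturbed solve")
      solve(M + 1e-12 * max(abs(M)) * I, ASn)
    })
    -2 * v[output]
  }, numeric(1))
}

#' Exact resolvent function G(s) of a linear network
#'
#' \eqn{G(s) = e_n^T (sI - A)^{-1} \Sigma e_n}; the PSD is
#' \eqn{2\,\mathrm{Re}\,G(i\omega)}.
#'
#' @inheritParams psd_exact
#' @param s Numeric or complex vector.
#' @export
linear_G <- function(lin, s, output = lin$output) {
  Sn <- lin$Sigma[, output]
  vapply(seq_along(s), function(i) {
    M <- diag(lin$d) * s[i] - lin$A
    v <- solve(M, Sn)
    v[output]
  }, if (is.complex(s)) complex(1) else numeric(1))
}

#' Exact Pade derivatives of a linear network
#'
#' Closed-form derivative values \eqn{D_m^{(s)} = (-1)^m e_n^T
#' (sI-A)^{-(m+1)} \Sigma e_n} and \eqn{D_m^{(\infty)} = e_n^T A^m \Sigma
#' e_n}, packaged like a `"pade_derivative_set"` so they can be fed to
#' [pade_solve()]; useful as an exact oracle.
#'
#' @inheritParams psd_exact
#' @param s Interpolation points (may include `Inf`).
#' @param rho Match counts.
#' @export
linear_derivatives <- function(lin, s, rho, output = lin$output) {
  points <- vector("list", length(s))
  Sn <- lin$Sigma[, output]
  for (i in seq_along(s)) {
    D <- numeric(rho[i])
    if (is.infinite(s[i])) {
      v <- Sn
      for (m in seq_len(rho[i]) - 1L) {
        D[m + 1L] <- v[output]
        v <- lin$A %*% v
      }
    } else {
      M <- diag(lin$d) * s[i] - lin$A
      v <- Sn
      for (m in seq_len(rho[i]) - 1L) {
        v <- solve(M, v)
        D[m + 1L] <- (-1)^m * v[output]
      }
    }
    points[[i]] <- list(s = s[i], D = D)
  }
  structure(list(s = s, rho = as.integer(rho), points = points,
                 variance = lin$Sigma[output, output], mean = lin$xbar[output]),
            class = "pade_derivative_set")
}

#' Exact PSD as a ratio of polynomials in omega^2
#'
#' Expresses the linear-network PSD with a monic denominator
#' \eqn{\det(\omega^2 I + A^2)}; the numerator is recovered by polynomial
#' interpolation.  This is the form in which small-network PSDs are
#' conventionally tabulated.
#'
#' @inheritParams psd_exact
#' @return A `"psd_rational"` (ascending coefficients in \eqn{u=\omega^2}).
#' @export
psd_rational_exact <- function(lin, output = lin$output) {
  d <- lin$d
  A2 <- lin$A %*% lin$A
  ev <- eigen(-A2, only.values = TRUE)$values
  den_u <- 1
  for (e in ev) den_u <- poly_mul(den_u, c(-e, 1))
  den_u <- Re(den_u)
  # numerator by interpolation at d positive u values
  us <- seq_len(d)
  Sv <- psd_exact(lin, sqrt(us), output = output)
  Nv <- Sv * vapply(us, function(u) Re(polyval_asc(den_u, u)), numeric(1))
  V <- outer(us, seq_len(d) - 1L, `^`)
  num_u <- as.numeric(solve(V, Nv))
  num_u <- zapsmall_coef(num_u)
  structure(list(num_u = num_u, den_u = zapsmall_coef(den_u)),
            class = "psd_rational")
}

zapsmall_coef <- function(x, tol = 1e-9) {
  m <- max(abs(x))
  ifelse(abs(x) < tol * m, 0, x)
}

# ---- PSD decomposition for stimulated linear networks -------------------

#' Describe an external stimulating signal
#'
#' A zeroth-order stimulation reaction `0 -> sum_j c_j X_j` firing at rate
#' \eqn{\theta\,Y(t)}, where the driving signal `Y` is an ergodic process
#' with stationary mean `mean` and power spectral density `psd`.
#'
#' @param theta Positive rate constant.
#' @param creation Non-negative integer creation vector `c` (length d of
#'   the downstream network).
#' @param psd PSD of the driving signal: function, `"rational_psd"`,
#'   `"psd_rational"` or `"linear_network"`.
#' @param mean Stationary mean of the driving signal.
#' @export
input_signal <- function(theta, creation, psd, mean) {
  stopifnot(theta > 0, all(creation >= 0), is.numeric(mean))
  structure(list(theta = theta, creation = as.numeric(creation),
                 psd = as_psd_function(psd), mean = mean),
            class = "input_signal")
}

#' Decompose the output PSD of a stimulated linear network
#'
#' For a linear network driven by independent ergodic signals through
#' zeroth-order creation reactions, the output PSD splits additively into
#' the intrinsic spectrum (the network with every input frozen at its
#' stationary mean) plus one gain-modulated term per input:
#' \deqn{S_{X_n}(\omega) = -2 e_n^T(\omega^2 I + A^2)^{-1}A\bar\Sigma e_n
#'   + \sum_j \theta_j^2 \,|e_n^T (A + i\omega I)^{-1} c_j|^2\,
#'     S_{Y_j}(\omega).}
#'
#' @param lin `"linear_network"` of the downstream network with each input
#'   frozen at its mean (i.e. including a constant creation reaction at
#'   rate `theta_j * mean_j`).
#' @param inputs List of [input_signal()] objects.
#' @param omega Frequency vector.
#' @param output Output species index.
#' @return Tibble with columns `omega`, `intrinsic`, one `extrinsic_*`
#'   column per input, and `total`.
#' @export
psd_decompose <- function(lin, inputs, omega, output = lin$output) {
  if (inherits(inputs, "input_signal")) inputs <- list(inputs)
  intr <- psd_exact(lin, omega, output = output)
  out <- tibble::tibble(omega = omega, intrinsic = intr)
  total <- intr
  I <- diag(lin$d)
  for (j in seq_along(inputs)) {
    inp <- inputs[[j]]
    gain <- vapply(omega, function(w) {
      v <- solve(lin$A + 1i * w * I, inp$creation)
      Mod(v[output])^2
    }, numeric(1))
    ext <- inp$theta^2 * gain * inp$psd(omega)
    out[[paste0("extrinsic_", j)]] <- ext
    total <- total + ext
  }
  out$total <- total
  out
}

#' Composite PSD: linear circuit driven by an upstream spectrum
#'
#' The PSD of a linear downstream circuit stimulated by one upstream signal
#' whose spectrum was obtained separately (analytically or by the
#' semi-analytic rational estimator): the isolated-circuit PSD plus the
#' gain-modulated upstream PSD.  No simulation of the combined process is
#' needed, so sweeping interconnection parameters is essentially free.
#'
#' @inheritParams psd_decompose
#' @param input A single [input_signal()] carrying the upstream PSD.
#' @return Tibble with `omega`, `intrinsic` (isolated circuit),
#'   `extrinsic_1` and `total`.
#' @export
composite_psd <- function(lin, input, omega, output = lin$output) {
  psd_decompose(lin, list(input), omega, output = output)
}

#' Oscillation criterion for the three-node negative-feedback circuit
#'
#' For the NFB topology with linearised feedback \eqn{F_b(x_o) = \beta_0 -
#' \beta_{fb} x_o}, the output PSD has a positive local (and global)
#' maximum, i.e. the circuit oscillates, if and only if
#' \eqn{k_o \beta_{fb} I_0} strictly exceeds a threshold depending only on
#' \eqn{\gamma_c, \gamma_o, k_o}.
#'
#' @param gamma_c,gamma_o Controller and output degradation rates.
#' @param k_o Output production rate constant.
#' @param beta_fb Feedback strength.
#' @param I0 Input abundance level.
#' @return Logical: does the output PSD peak at a positive frequency?
#' @export
nfb_oscillation_criterion <- function(gamma_c, gamma_o, k_o, beta_fb, I0) {
  stopifnot(gamma_c > 0, gamma_o > 0, k_o > 0, beta_fb >= 0, I0 >= 0)
  Gam <- (gamma_c * gamma_o + gamma_c^2 + k_o * gamma_c)^2 +
    gamma_c^4 + gamma_c^3 * k_o + gamma_o^2 * gamma_c * k_o
  thr <- (gamma_c^4 + gamma_c^3 * k_o + gamma_o^2 * gamma_c * k_o) /
    (sqrt(Gam) + gamma_c * gamma_o + gamma_c^2 + k_o * gamma_c)
  k_o * beta_fb * I0 > thr
}
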