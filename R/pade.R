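# ---- small polynomial utilities (ascending coefficient vectors) --------

polyval_asc <- function(coef, x) {
  out <- rep_len(if (is.complex(coef) || is.complex(x)) 0i else 0, length(x))
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

poly_mul <- function(a, b) {
  out <- rep_len(if (is.complex(a) || is.complex(b)) 0i else 0,
                 length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# ---- linear system blocks (multipoint Pade interpolation) ---------------

#' Build one interpolation block of the Pade linear system
#'
#' For the rational ansatz \eqn{G_p(s) = (\kappa_0 + \cdots +
#' \kappa_{p-1}s^{p-1}) / (\beta_0 + \cdots + \beta_{p-1}s^{p-1} + s^p)},
#' matching the first \eqn{\rho_\ell} power-series terms of \eqn{G} at
#' \eqn{s_\ell} gives a \eqn{\rho_\ell \times 2p} linear block in the
#' unknown coefficient vector \eqn{(\kappa, \beta)}.  The entries carry
#' binomial weights and powers of \eqn{s_\ell}; at \eqn{s_\ell = \infty}
#' the block matches the expansion in powers of \eqn{1/s}.
#'
#' @param s Interpolation point (finite positive or `Inf`).
#' @param D Derivatives `D_0 .. D_{rho-1}` at the point.
#' @param p Order of the approximant (`>= 1`).
#' @return List with matrix `A` (`rho x 2p`) and vector `b`.
#' @export
pade_block <- function(s, D, p) {
  if (p < 1) stop("order p must be >= 1")
  rho <- length(D)
  A <- matrix(0, rho, 2 * p)
  b <- numeric(rho)
  if (is.infinite(s)) {
    for (j in seq_len(rho) - 1L) {
      if (j <= p - 1L) A[j + 1L, (p - 1L - j) + 1L] <- 1
      if (j >= 1L) {
        for (i in seq(max(p, 2L * p - j), 2L * p - 1L)) {
          A[j + 1L, i + 1L] <- -D[(j + i - 2L * p) + 1L]
        }
      }
      b[j + 1L] <- D[j + 1L]
    }
  } else {
    for (j in seq_len(rho) - 1L) {
      if (j <= p - 1L) for (i in seq(j, p - 1L)) {
        A[j + 1L, i + 1L] <- choose(i, j) * s^(i - j)
      }
      for (i in seq(p, 2L * p - 1L)) {
        ks <- 0:min(i - p, j)
        A[j + 1L, i + 1L] <- -sum(choose(i - p, ks) * s^(i - p - ks) *
                                    D[(j - ks) + 1L])
      }
      b[j + 1L] <- sum(choose(p, 0:j) * s^(p - (0:j)) * D[(j - (0:j)) + 1L])
    }
  }
  list(A = A, b = b)
}

stack_system <- function(derivs, p) {
  blocks <- lapply(derivs$points, function(pt) pade_block(pt$s, pt$D, p))
  list(A = do.call(rbind, lapply(blocks, `[[`, "A")),
       b = unlist(lapply(blocks, `[[`, "b")))
}

# Column-scaled least squares with a relative singular-value cutoff.
ls_solve <- function(A, b, cutoff = 1e-10) {
  scale <- apply(abs(A), 2L, max)
  scale[scale == 0] <- 1
  As <- sweep(A, 2L, scale, "/")
  sv <- svd(As)
  keep <- sv$d > cutoff * max(sv$d)
  if (!all(keep))
    warning("Pade linear system numerically rank-deficient; ",
            "solved via pseudoinverse")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  x <- sv$v %*% (dinv * crossprod(sv$u, b))
  as.numeric(x / scale)
}

#' Solve the multipoint Pade system for the rational approximant
#'
#' Stacks the per-point blocks into a cumulative linear system and solves
#' it in the least-squares sense (under- and over-determined cases alike).
#' With a known denominator factor \eqn{B(s)} of degree `q` (e.g. the
#' significant eigenvalue pair of an upstream process or of the cell-cycle
#' clock) the system is transformed with the convolution matrix of `B` and
#' only the remaining \eqn{p - q} denominator coefficients are estimated.
#'
#' @param derivs A `"pade_derivative_set"` (or a list with a `points` field
#'   of `list(s =, D =)` entries).
#' @param p Approximant order.
#' @param known_factor Optional coefficients `c(B_0, ..., B_{q-1})` of a
#'   monic factor \eqn{B(s) = B_0 + \cdots + B_{q-1}s^{q-1} + s^q}.
#' @param cutoff Relative singular-value cutoff of the least-squares solve.
#' @return A `"rational_psd"`: the approximant \eqn{G_p} with numerator
#'   `kappa`, full monic denominator `den`, its roots and a stability flag
#'   (all roots in the open left half-plane).  The PSD is
#'   \eqn{S(\omega) = 2\,\mathrm{Re}\,G_p(i\omega)}.
#' @export
pade_solve <- function(derivs, p, known_factor = NULL, cutoff = 1e-10) {
  sys <- stack_system(derivs, p)
  A <- sys$A; b <- sys$b
  if (is.null(known_factor) || length(known_factor) == 0) {
    x <- ls_solve(A, b, cutoff)
    kappa <- x[seq_len(p)]
    den <- c(x[p + seq_len(p)], 1)
    beta_free <- x[p + seq_len(p)]
    q <- 0L; B <- numeric(0)
  } else {
    B <- as.numeric(known_factor)
    q <- length(B)
    if (q > p) stop("degree of the known factor exceeds p")
    Bfull <- c(B, 1)
    C <- matrix(0, p, p - q)
    for (j in seq_len(p) - 1L) for (i in seq_len(p - q) - 1L) {
      if (j - i >= 0 && j - i <= q) C[j + 1L, i + 1L] <- Bfull[j - i + 1L]
    }
    v <- numeric(p)
    for (j in seq_len(p) - 1L) {
      if (j - (p - q) >= 0) v[j + 1L] <- Bfull[j - (p - q) + 1L]
    }
    M <- cbind(A[, seq_len(p), drop = FALSE],
               A[, p + seq_len(p), drop = FALSE] %*% C)
    rhs <- b - A %*% c(numeric(p), v)
    x <- ls_solve(M, as.numeric(rhs), cutoff)
    kappa <- x[seq_len(p)]
    beta_free <- if (p - q > 0) x[p + seq_len(p - q)] else numeric(0)
    den <- poly_mul(c(beta_free, 1), Bfull)
  }
  roots <- polyroot(den)
  structure(list(kappa = kappa, den = den, beta_free = beta_free,
                 B = B, p = p, q = q, roots = roots,
                 stable = all(Re(roots) < 0)),
            class = "rational_psd")
}

#' @export
print.rational_psd <- function(x, ...) {
  cat("<rational_psd> order p = ", x$p,
      if (x$q > 0) paste0(" (known factor degree ", x$q, ")"),
      "; stable: ", x$stable, "\n", sep = "")
  cat("  numerator:  ", paste(format(x$kappa, digits = 5), collapse = ", "),
      "\n  denominator:", paste(format(x$den, digits = 5), collapse = ", "),
      " (ascending, monic)\n")
  invisible(x)
}

#' Evaluate the rational approximant G_p(s)
#' @param rational A `"rational_psd"`.
#' @param s Numeric or complex vector.
#' @export
G_eval <- function(rational, s) {
  polyval_asc(rational$kappa, s) / polyval_asc(rational$den, s)
}

#' Evaluate the PSD of a rational approximant
#'
#' \eqn{S(\omega) = 2\,\mathrm{Re}\,G_p(i\omega)}.  Imperfect approximants
#' can dip below zero at some frequencies; raw values are returned by
#' default, `clip = TRUE` floors them at zero.  Evaluation at a purely
#' imaginary denominator root yields `Inf`.
#'
#' @param rational A `"rational_psd"` or `"psd_rational"` object.
#' @param omega Frequency vector (rad / time unit).
#' @param clip Floor negative values at zero.
#' @export
psd_eval <- function(rational, omega, clip = FALSE) {
  v <- if (inherits(rational, "psd_rational")) {
    u <- omega^2
    polyval_asc(rational$num_u, u) / polyval_asc(rational$den_u, u)
  } else {
    2 * Re(G_eval(rational, 1i * omega))
  }
  if (clip) pmax(v, 0) else v
}

#' Express a PSD as a ratio of polynomials in omega^2
#'
#' Converts \eqn{S(\omega) = 2\,\mathrm{Re}\,G_p(i\omega)} into the form
#' \eqn{P(\omega^2)/Q(\omega^2)} with `Q` monic of degree `p`, the form in
#' which analytic PSDs of small networks are usually reported.
#'
#' @param rational A `"rational_psd"`.
#' @return A `"psd_rational"`: ascending coefficient vectors `num_u` and
#'   `den_u` in the variable \eqn{u = \omega^2}.
#' @export
psd_polynomial <- function(rational) {
  p <- rational$p
  kap <- rational$kappa; den <- rational$den
  iN <- kap * (1i)^(seq_along(kap) - 1L)      # N(i w) coefficients in w
  iDc <- den * (-1i)^(seq_along(den) - 1L)    # D(-i w)
  num_w <- 2 * Re(poly_mul(iN, iDc))
  den_w <- Re(poly_mul(den * (1i)^(seq_along(den) - 1L), iDc))
  # odd powers vanish identically; collect even powers as powers of u
  num_u <- num_w[seq(1L, length(num_w), by = 2L)]
  den_u <- den_w[seq(1L, length(den_w), by = 2L)]
  num_u <- num_u[seq_len(p)]
  den_u <- den_u / den_u[p + 1L]
  structure(list(num_u = num_u, den_u = den_u), class = "psd_rational")
}

#' @export
print.psd_rational <- function(x, ...) {
  cat("<psd_rational> S(w) = P(w^2)/Q(w^2)\n  P: ",
      paste(format(x$num_u, digits = 6), collapse = ", "),
      "\n  Q: ", paste(format(x$den_u, digits = 6), collapse = ", "),
      " (ascending, monic)\n", sep = "")
  invisible(x)
}

as_psd_function <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "rational_psd") || inherits(x, "psd_rational"))
    return(function(omega) psd_eval(x, omega))
  if (inherits(x, "linear_network"))
    return(function(omega) psd_exact(x, omega))
  stop("cannot interpret object as a PSD")
}

#' Validate a Pade approximant against direct resolvent estimates
#'
#' Compares \eqn{G_p(\bar s_r)} with the direct Monte Carlo estimates
#' \eqn{\hat G(\bar s_r)}; a point passes when its relative error is below
#' `threshold` or the absolute gap is within 3 standard errors of the
#' direct estimate, and the approximant passes when every point does.
#'
#' @param rational A `"rational_psd"`.
#' @param direct List with `s`, `G`, `se` (see [direct_G_estimates()]), or
#'   a `"pade_derivative_set"`.
#' @param threshold Relative-error threshold (default 10%).
#' @return A tibble with per-point errors; attribute `"pass"` gives the
#'   overall verdict.
#' @export
validate_pade <- function(rational, direct, threshold = 0.1) {
  if (inherits(direct, "pade_derivative_set")) direct <- direct$direct
  if (is.null(direct) || length(direct$s) == 0) stop("no test points")
  Gp <- Re(G_eval(rational, direct$s))
  abs_err <- abs(Gp - direct$G)
  rel_err <- abs_err / abs(direct$G)
  se <- if (is.null(direct$se)) rep(NA_real_, length(Gp)) else direct$se
  ok <- rel_err <= threshold | (!is.na(se) & abs_err <= 3 * se)
  out <- tibble::tibble(s = direct$s, G_direct = direct$G, G_pade = Gp,
                        abs_err = abs_err, rel_err = rel_err, se = se,
                        pass = ok)
  attr(out, "pass") <- all(ok)
  out
}

#' Locate the PSD peak frequency
#'
#' Global maximiser of the PSD over `[0, omega_hi]` found on a refined grid
#' and polished locally; `0` means the spectrum is non-oscillatory (the
#' global maximum sits at the origin).
#'
#' @param x A PSD: function of omega, `"rational_psd"`, `"psd_rational"`
#'   or `"linear_network"`.
#' @param omega_hi Upper search bound; chosen from the denominator roots
#'   for rational objects.
#' @param omega_lo Lower search bound (default 0).  A positive value
#'   locates an off-zero local peak, e.g. the cell-cycle resonance riding
#'   on a decreasing background.
#' @param n_grid Grid resolution.
#' @export
peak_frequency <- function(x, omega_hi = NULL, omega_lo = 0, n_grid = 4000) {
  f <- as_psd_function(x)
  if (is.null(omega_hi)) {
    omega_hi <- if (inherits(x, "rational_psd")) {
      4 * max(1, Mod(x$roots))
    } else if (inherits(x, "psd_rational")) {
      4 * max(1, sqrt(Mod(polyroot(x$den_u))))
    } else if (inherits(x, "linear_network")) {
      4 * max(1, Mod(eigen(x$A, only.values = TRUE)$values))
    } else 20
  }
  grid <- seq(omega_lo, omega_hi, length.out = n_grid)
  vals <- f(grid)
  i <- which.max(vals)
  if (i == 1L) return(0)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  # the maximum must beat the window's left edge to count as a peak
  if (opt$objective <= f(omega_lo) * (1 + 1e-12)) 0 else opt$maximum
}

#' Entrainment score: band power near a driver frequency
#'
#' Fraction of the total signal power falling in the band
#' `[0.9, 1.1] * omega0` around the driving oscillator's natural frequency:
#' \eqn{\int_{0.9\omega_0}^{1.1\omega_0} S \,/\, \int_0^\infty S}.
#' Requires an integrable PSD (for rational PSDs, numerator degree below
#' denominator degree).
#'
#' @param x PSD object or function.
#' @param omega0 Driver frequency (`> 0`).
#' @param band Relative band edges (default `c(0.9, 1.1)`).
#' @export
entrainment_score <- function(x, omega0, band = c(0.9, 1.1)) {
  stopifnot(omega0 > 0, length(band) == 2, band[1] <= band[2])
  f <- as_psd_function(x)
  if (inherits(x, "rational_psd")) {
    if (length(x$kappa) >= length(x$den))
      stop("PSD not integrable: numerator degree too high")
  }
  total <- stats::integrate(f, 0, Inf, rel.tol = 1e-9)
  if (!is.finite(total$value) || total$value <= 0)
    stop("PSD not integrable on [0, Inf)")
  if (band[1] == band[2]) return(0)
  bandint <- stats::integrate(f, band[1] * omega0, band[2] * omega0,
                              rel.tol = 1e-9)
  bandint$value / total$value
}

#' Peak quality: peak frequency over half-power bandwidth
#'
#' A simple sharpness measure of an oscillatory PSD: \eqn{\omega_{max}}
#' divided by the width of the interval around the peak where the PSD stays
#' above half its peak value.  Returns 0 for non-oscillatory spectra.
#'
#' @inheritParams peak_frequency
#' @export
peak_quality <- function(x, omega_hi = NULL, n_grid = 4000) {
  f <- as_psd_function(x)
  wmax <- peak_frequency(x, omega_hi = omega_hi, n_grid = n_grid)
  if (wmax == 0) return(0)
  smax <- f(wmax)
  half <- smax / 2
  lo <- wmax; hi <- wmax
  step <- wmax / 200
  while (lo > 0 && f(lo) > half) lo <- lo - step
  while (f(hi) > half && hi < wmax * 20) hi <- hi + step
  wmax / (hi - lo)
}

#' Run the full semi-analytic PSD pipeline
#'
#' Simulates the augmented chain, estimates the Pade derivatives, solves
#' for the rational approximant and validates it against the direct
#' resolvent estimates at the test points.
#'
#' @inheritParams pade_derivatives
#' @param p Approximant order.
#' @param known_factor Optional known monic denominator factor
#'   (see [pade_solve()]).
#' @param threshold Validation relative-error threshold.
#' @return A `"pade_psd_fit"`: list with `rational`, `derivatives`,
#'   `validation` and the run configuration.
#' @export
pade_psd <- function(network, p = 2, s = Inf, rho = 4,
                     s_test = c(0.5, 1, 2), Q = 10, Tf = 1e4, Tc = 1e2,
                     seed = 1, known_factor = NULL,
                     infinity = c("covariate", "naive"),
                     threshold = 0.1, state0 = NULL) {
  derivs <- pade_derivatives(network, s = s, rho = rho, s_test = s_test,
                             Q = Q, Tf = Tf, Tc = Tc, seed = seed,
                             infinity = infinity, state0 = state0)
  rational <- pade_solve(derivs, p = p, known_factor = known_factor)
  validation <- if (length(s_test) > 0)
    validate_pade(rational, derivs, threshold = threshold) else NULL
  structure(list(rational = rational, derivatives = derivs,
                 validation = validation,
                 config = list(p = p, s = s, rho = rho, s_test = s_test,
                               Q = Q, Tf = Tf, Tc = Tc, seed = seed,
                               known_factor = known_factor,
                               threshold = threshold)),
            class = "pade_psd_fit")
}

#' @export
print.pade_psd_fit <- function(x, ...) {
  print(x$rational)
  if (!is.null(x$validation))
    cat("  validation:", if (isTRUE(attr(x$validation, "pass")))
      "PASS" else "FAIL", "\n")
  invisible(x)
}
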