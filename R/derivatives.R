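# Estimators of the Pade derivatives D_m^(s): the Taylor coefficients of
# the resolvent function G(s) = E_pi[f R(s) f] at the interpolation points.
# Finite points use the Erlang-lag identity
#   D_m^(s) = (-1)^m / s^(m+1) * (Var_pi(X_n) - delta_m / 2),
# with delta_m the stationary mean squared gap between the output and its
# (m+1)-th shift register; the infinity point uses generator moments
# D_m^(inf) = E_pi[f A^m f], either directly ("naive") or through the
# variance-reduced covariate integrand Psi_m ("covariate").

batch_se <- function(v) {
  if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
}

#' Finite-point Pade derivatives from an augmented ensemble
#'
#' @param ensemble A `"ctmc_ensemble"` of an [augment()]ed network.
#' @param l Index of the finite interpolation point.
#' @return List with `D` (values `D_0 .. D_{rho_l - 1}`), `se`, and the
#'   register gap estimates `delta` with their `delta_se`.
#' @export
finite_point_derivatives <- function(ensemble, l) {
  net <- ensemble$network
  a <- augmentation_info(net)
  if (is.null(a) || l > length(a$s_points)) stop("missing shift registers")
  s <- a$s_points[l]
  rho <- a$rho[l]
  b <- ensemble_batches(ensemble)
  mv <- stationary_mean_variance(ensemble)
  D <- se <- delta <- delta_se <- numeric(rho)
  for (m in seq_len(rho) - 1L) {
    col <- a$offsets[l] + m + 1L
    delta_b <- b$int_reg[, col] / b$t_eff
    delta_hat <- sum(b$int_reg[, col]) / sum(b$t_eff)
    Db <- (-1)^m / s^(m + 1) * (mv$batch_variance - delta_b / 2)
    D[m + 1L] <- (-1)^m / s^(m + 1) * (mv$variance - delta_hat / 2)
    se[m + 1L] <- batch_se(Db)
    delta[m + 1L] <- delta_hat
    delta_se[m + 1L] <- batch_se(delta_b)
  }
  list(s = s, D = D, se = se, delta = delta, delta_se = delta_se)
}

#' Direct resolvent estimates at the validation points
#'
#' \eqn{\hat G(\bar s_r) = [\widehat{Var} - \tfrac12\langle (Z_r - X_n)^2
#' \rangle] / \bar s_r} from the snapshot registers.
#'
#' @inheritParams finite_point_derivatives
#' @return List with `s`, `G` and `se`.
#' @export
direct_G_estimates <- function(ensemble) {
  net <- ensemble$network
  a <- augmentation_info(net)
  if (is.null(a) || length(a$test_points) == 0) stop("missing Z registers")
  b <- ensemble_batches(ensemble)
  mv <- stationary_mean_variance(ensemble)
  ny <- sum(a$rho)
  R <- length(a$test_points)
  G <- se <- numeric(R)
  for (r in seq_len(R)) {
    col <- ny + r
    gap_b <- b$int_reg[, col] / b$t_eff
    gap <- sum(b$int_reg[, col]) / sum(b$t_eff)
    Gb <- (mv$batch_variance - gap_b / 2) / a$test_points[r]
    G[r] <- (mv$variance - gap / 2) / a$test_points[r]
    se[r] <- batch_se(Gb)
  }
  list(s = a$test_points, G = G, se = se)
}

# Evaluate a per-state integrand over the ensemble's unique-state table.
# fvals: numeric vector, one value per table row.  Returns pooled mean and
# per-batch means.
table_average <- function(tab, t_eff, fvals) {
  per_batch <- as.numeric(crossprod(tab$weights, fvals)) / t_eff
  pooled <- sum(fvals * rowSums(tab$weights)) / sum(t_eff)
  list(pooled = pooled, batch = per_batch)
}

#' Infinity-point Pade derivatives, naive estimator
#'
#' Time average of \eqn{f \cdot \mathbb{A}^m f} along the paths, with
#' \eqn{f} centred at the ensemble's estimated stationary mean.  Exact for
#' `m = 0` (it reduces to the pooled variance estimator) but high-variance
#' for larger `m`; kept as a diagnostic, see
#' [infinity_derivatives_covariate()] for the default.
#'
#' @param ensemble A `"ctmc_ensemble"` simulated with `record_table = TRUE`.
#' @param rho Number of derivatives `D_0 .. D_{rho-1}`.
#' @return List with `D` and `se`.
#' @export
infinity_derivatives_naive <- function(ensemble, rho) {
  net <- ensemble$network
  tab <- ensemble_state_table(ensemble)
  b <- ensemble_batches(ensemble)
  mv <- stationary_mean_variance(ensemble)
  ns <- nrow(tab$states)
  D <- se <- numeric(rho)
  f0 <- tab$states[, net$output] - mv$mean
  av_all <- amf_on_states(net, tab$states, rho - 1L, mv$mean)
  for (m in seq_len(rho) - 1L) {
    ta <- table_average(tab, b$t_eff, f0 * av_all[, m + 1L])
    D[m + 1L] <- ta$pooled
    se[m + 1L] <- batch_se(ta$batch)
  }
  D[1L] <- mv$variance  # m = 0: identical to the pooled variance estimator
  se[1L] <- mv$variance_se
  list(D = D, se = se)
}

# A^m f for m = 0..m_max on a state matrix: vectorised when displacements
# are fixed, per-state recursion otherwise.
amf_on_states <- function(network, states, m_max, center) {
  fixed <- !any(vapply(network$reactions,
                       function(r) !is.null(r$kernel), TRUE))
  if (fixed) {
    tb <- amf_table(network, states, m_max, center)
    return(tb$vals[tb$idx, , drop = FALSE])
  }
  amf <- generator_power_evaluator(network, center = center)
  ns <- nrow(states)
  vapply(seq_len(m_max + 1L), function(mi)
    vapply(seq_len(ns), function(i) amf(mi - 1L, states[i, ]), numeric(1)),
    numeric(ns))
}

#' Infinity-point Pade derivatives, covariate estimator
#'
#' Default estimator for the derivatives at \eqn{s = \infty}: time averages
#' of the covariate integrand \eqn{\Psi_m}, whose stationary mean equals
#' \eqn{E_\pi[f\,\mathbb{A}^m f]} but whose Monte Carlo variance is far
#' smaller than the naive product's.  `D_0` is the stationary variance and
#' is always taken from the pooled variance estimator.
#'
#' @inheritParams infinity_derivatives_naive
#' @export
infinity_derivatives_covariate <- function(ensemble, rho) {
  net <- ensemble$network
  mv <- stationary_mean_variance(ensemble)
  D <- se <- numeric(rho)
  D[1L] <- mv$variance; se[1L] <- mv$variance_se
  if (rho > 1L) {
    tab <- ensemble_state_table(ensemble)
    b <- ensemble_batches(ensemble)
    fixed <- !any(vapply(net$reactions,
                         function(r) !is.null(r$kernel), TRUE))
    tb <- if (fixed) amf_table(net, tab$states, rho - 1L, mv$mean)
    amf <- if (!fixed) generator_power_evaluator(net, center = mv$mean)
    ns <- nrow(tab$states)
    for (m in seq_len(rho - 1L)) {
      pv <- if (fixed) psi_vec(tb, m)
      else vapply(seq_len(ns),
                  function(i) psi_covariate(net, m, tab$states[i, ], amf),
                  numeric(1))
      ta <- table_average(tab, b$t_eff, pv)
      D[m + 1L] <- ta$pooled
      se[m + 1L] <- batch_se(ta$batch)
    }
  }
  list(D = D, se = se)
}

#' Estimate all Pade derivatives for a network
#'
#' Convenience wrapper: augments the network with the required shift and
#' snapshot registers, simulates `Q` trajectories of the augmented chain,
#' and returns every derivative needed by [pade_solve()] together with the
#' direct validation estimates.
#'
#' @param network A [reaction_network()] (not yet augmented).
#' @param s Interpolation points; use `Inf` for the generator-moment point.
#' @param rho Match counts, same length as `s`.
#' @param s_test Validation points.
#' @param Q,Tf,Tc,seed Ensemble settings (see [ssa_ensemble()]).
#' @param infinity One of `"covariate"` (default) or `"naive"`.
#' @param state0 Initial base state.
#' @return A `"pade_derivative_set"`.
#' @export
pade_derivatives <- function(network, s = Inf, rho = 4,
                             s_test = c(0.5, 1, 2),
                             Q = 10, Tf = 1e4, Tc = 1e2, seed = 1,
                             infinity = c("covariate", "naive"),
                             state0 = NULL) {
  infinity <- match.arg(infinity)
  stopifnot(length(s) == length(rho))
  if (anyDuplicated(s)) stop("duplicate interpolation points")
  fin <- is.finite(s)
  rho <- as.integer(rho)
  aug <- augment(network, s_points = s[fin], rho = rho[fin],
                 test_points = s_test)
  need_table <- any(!fin) && rho[!fin][1] >= 1L
  ens <- ssa_ensemble(aug, Q = Q, Tf = Tf, Tc = Tc, seed = seed,
                      record_table = need_table, state0 = state0)
  mv <- stationary_mean_variance(ens)
  points <- vector("list", length(s))
  for (i in seq_along(s)) {
    if (fin[i]) {
      l <- match(s[i], s[fin])
      points[[i]] <- finite_point_derivatives(ens, l)
    } else {
      est <- if (infinity == "covariate")
        infinity_derivatives_covariate(ens, rho[i])
      else infinity_derivatives_naive(ens, rho[i])
      points[[i]] <- list(s = Inf, D = est$D, se = est$se)
    }
  }
  direct <- if (length(s_test) > 0) direct_G_estimates(ens) else NULL
  structure(list(s = s, rho = rho, points = points,
                 variance = mv$variance, variance_se = mv$variance_se,
                 mean = mv$mean, mean_se = mv$mean_se,
                 direct = direct,
                 Q = Q, Tf = Tf, Tc = Tc, seed = seed,
                 network = network),
            class = "pade_derivative_set")
}

#' @export
print.pade_derivative_set <- function(x, ...) {
  cat("<pade_derivative_set> points:",
      paste0("s=", format(x$s), " (rho=", x$rho, ")", collapse = ", "), "\n")
  cat("  output mean ", format(x$mean), " (se ", format(x$mean_se),
      "), variance ", format(x$variance), " (se ", format(x$variance_se),
      ")\n", sep = "")
  invisible(x)
}

#' Tidy a derivative set into a tibble
#' @param x A `"pade_derivative_set"`.
#' @param ... Unused.
#' @export
tidy.pade_derivative_set <- function(x, ...) {
  rows <- do.call(rbind, lapply(seq_along(x$s), function(i) {
    p <- x$points[[i]]
    data.frame(s = x$s[i], m = seq_along(p$D) - 1L,
               estimate = p$D, se = p$se)
  }))
  out <- tibble::as_tibble(rows)
  if (!is.null(x$direct)) {
    out <- rbind(out,
      tibble::tibble(s = x$direct$s, m = NA_integer_,
                     estimate = x$direct$G, se = x$direct$se))
  }
  out
}
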