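# Nonparametric periodogram estimator of the PSD: sample the
# piecewise-constant trajectory on a uniform grid, take the DFT and scale
# by dt/N so the estimate targets the continuous-time two-sided spectrum.

#' Sample a trajectory on a uniform time grid
#'
#' Evaluates the right-continuous piecewise-constant path of the output
#' species at `Tc + k*dt` for `k = 0, ..., N-1` with
#' `N = floor((Tf - Tc)/dt)` (half-open window).  A warning is issued when
#' `dt` is large relative to the fastest propensity timescale at the
#' initial state, the standard aliasing heuristic.
#'
#' @param trajectory A `"ctmc_trajectory"`.
#' @param dt Sampling step, `0 < dt < (Tf - Tc)/2`.
#' @param Tc,Tf Sampling window.
#' @param species Species index to sample (default: the output species).
#' @return A `"sampled_series"`: list with `values`, `dt`,
#'   `mean_subtracted = FALSE`.
#' @export
sample_series <- function(trajectory, dt, Tc = 0, Tf = NULL,
                          species = NULL) {
  if (is.null(Tf)) Tf <- trajectory$Tf
  if (Tc >= Tf) stop("empty sampling window")
  if (dt <= 0 || dt >= (Tf - Tc) / 2) stop("dt must be in (0, (Tf-Tc)/2)")
  if (is.null(species)) species <- trajectory$network$output
  n <- floor((Tf - Tc) / dt)
  grid <- Tc + (seq_len(n) - 1L) * dt
  idx <- findInterval(grid, trajectory$times)
  vals <- trajectory$states[idx, species]
  a0 <- sum(all_propensities(trajectory$network,
                             trajectory$states[1, seq_len(trajectory$network$d)]))
  if (a0 > 0 && dt > 0.5 / a0)
    warning("sampling step dt exceeds half the fastest mean holding time; ",
            "the periodogram may be aliased")
  structure(list(values = as.numeric(vals), dt = dt,
                 mean_subtracted = FALSE),
            class = "sampled_series")
}

#' Periodogram of a sampled series
#'
#' Subtracts the sample mean and returns
#' \eqn{S(\omega_k) = \Delta t\,|{\rm DFT}(\tilde x)_k|^2 / N} on the
#' frequency grid \eqn{\omega_k = 2\pi k/(N \Delta t)}, an estimate of the
#' continuous-time two-sided PSD.  No windowing or smoothing is applied.
#' The estimator is asymptotically unbiased but inconsistent: its per-bin
#' variance does not vanish as the series grows, which is why ensemble
#' averaging is used in practice.
#'
#' @param series A `"sampled_series"` or numeric vector (then `dt` must be
#'   given).
#' @param dt Sampling step when `series` is a bare vector.
#' @return Tibble with columns `omega` (up to the Nyquist frequency
#'   \eqn{\pi/\Delta t}) and `psd`.
#' @export
periodogram <- function(series, dt = NULL) {
  if (inherits(series, "sampled_series")) {
    x <- series$values; dt <- series$dt
  } else {
    x <- as.numeric(series)
    if (is.null(dt)) stop("dt required for a bare numeric series")
  }
  n <- length(x)
  if (n < 2) stop("series too short")
  xt <- x - mean(x)
  S <- dt * Mod(stats::fft(xt))^2 / n
  omega <- 2 * pi * (seq_len(n) - 1L) / (n * dt)
  keep <- seq_len(floor(n / 2) + 1L)
  out <- tibble::tibble(omega = omega[keep], psd = S[keep])
  attr(out, "full_psd") <- S
  attr(out, "dt") <- dt
  out
}

#' Ensemble-averaged periodogram of a network
#'
#' Simulates `Q` trajectories, samples each on a uniform grid over
#' `[Tc, Tf]` and averages the per-trajectory periodograms; the returned
#' band is the symmetric one-standard-deviation interval across
#' trajectories.
#'
#' @param network A [reaction_network()].
#' @param Q Number of trajectories.
#' @param dt Sampling step.
#' @param Tf,Tc Simulation horizon and burn-in.
#' @param seed Base seed (per-trajectory seeds split deterministically).
#' @param state0 Initial state.
#' @return Tibble with `omega`, `mean_psd`, `sd_psd`.
#' @export
ensemble_psd <- function(network, Q = 10, dt = 0.1, Tf = 1e3, Tc = 1e2,
                         seed = 1, state0 = NULL) {
  ens <- ssa_ensemble(network, Q = Q, Tf = Tf, Tc = Tc, seed = seed,
                      sample_dt = dt, state0 = state0)
  n <- floor((Tf - Tc) / dt)
  mats <- lapply(ens$runs, function(r) {
    v <- r$samples[seq_len(n), network$output]
    periodogram(v, dt = dt)$psd
  })
  M <- do.call(cbind, mats)
  pg <- periodogram(ens$runs[[1]]$samples[seq_len(n), network$output],
                    dt = dt)
  tibble::tibble(omega = pg$omega,
                 mean_psd = rowMeans(M),
                 sd_psd = apply(M, 1L, stats::sd))
}

#' Default aliasing-safe sampling step for a network
#'
#' One tenth of the mean holding time at the stationary (or supplied)
#' state, the package's default for periodogram sampling.
#'
#' @param network A [reaction_network()].
#' @param state State at which to evaluate the total propensity (defaults
#'   to `state0`).
#' @export
default_dt <- function(network, state = NULL) {
  if (is.null(state)) state <- network$state0
  a0 <- sum(all_propensities(network, state))
  if (a0 <= 0) stop("total propensity is zero at the reference state")
  0.1 / a0
}
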