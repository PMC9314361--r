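n_y_registers <- function(network) {
  a <- attr(network, "augmentation")
  if (is.null(a)) 0L else sum(a$rho)
}

n_z_registers <- function(network) {
  a <- attr(network, "augmentation")
  if (is.null(a)) 0L else length(a$test_points)
}

augmentation_info <- function(network) attr(network, "augmentation")

#' Augment a network with Erlang-lag shift registers and snapshot registers
#'
#' Builds the augmented CTMC used by the spectral estimators.  For every
#' finite interpolation point \eqn{s_\ell} a reset reaction firing at the
#' constant rate \eqn{s_\ell} is added; when it fires, a bank of
#' \eqn{\rho_\ell} registers shifts: the first register takes the current
#' output copy-number and each subsequent register takes its predecessor's
#' value.  At any time the \eqn{(m+1)}-th register then holds the output
#' copy-number an Erlang\eqn{(m+1, s_\ell)}-distributed lag in the past,
#' which is exactly the correlation needed for the \eqn{m}-th derivative of
#' the resolvent function at \eqn{s_\ell}.  For every test point
#' \eqn{\bar s_r} a snapshot reaction firing at rate \eqn{\bar s_r} copies
#' the output count into a single register, giving a direct estimate of
#' \eqn{G(\bar s_r)} for validation.  Base reactions never touch the
#' registers and the registers never feed back, so the law of the base
#' chain is unchanged.
#'
#' An infinite interpolation point contributes no registers (its
#' derivatives are generator moments); pass only the finite points here.
#'
#' @param network A [reaction_network()].
#' @param s_points Finite interpolation points, all `> 0`, distinct.
#' @param rho Match counts per finite point (integers `>= 1`).
#' @param test_points Validation points \eqn{\bar s_r > 0}, distinct.
#' @return An augmented `"reaction_network"`.
#' @export
augment <- function(network, s_points = numeric(), rho = integer(),
                    test_points = numeric()) {
  s_points <- as.numeric(s_points); test_points <- as.numeric(test_points)
  if (any(!is.finite(s_points)))
    stop("s_points must be finite; the infinity point needs no registers")
  if (length(s_points) != length(rho)) stop("s_points and rho lengths differ")
  if (any(s_points <= 0) || any(test_points <= 0))
    stop("interpolation and test points must be positive")
  if (anyDuplicated(s_points) || anyDuplicated(test_points))
    stop("duplicate interpolation or test points")
  rho <- as.integer(rho)
  if (any(rho < 1L)) stop("all match counts rho must be >= 1")
  if (!is.null(augmentation_info(network)))
    stop("network is already augmented")

  reactions <- network$reactions
  d <- network$d
  offs <- c(0L, cumsum(rho))
  for (l in seq_along(s_points)) {
    rr <- reaction(reactants = rep(0, d), displacement = rep(0, d),
                   propensity = const_propensity(s_points[l]),
                   name = paste0("reset_s", l))
    attr(rr, "register") <- list(type = "shift", start = offs[l] + 1L,
                                 len = rho[l], rate = s_points[l])
    reactions[[length(reactions) + 1L]] <- rr
  }
  for (r in seq_along(test_points)) {
    rr <- reaction(reactants = rep(0, d), displacement = rep(0, d),
                   propensity = const_propensity(test_points[r]),
                   name = paste0("snapshot_", r))
    attr(rr, "register") <- list(type = "snapshot", idx = r,
                                 rate = test_points[r])
    reactions[[length(reactions) + 1L]] <- rr
  }
  out <- network
  out$reactions <- reactions
  attr(out, "augmentation") <- list(
    s_points = s_points, rho = rho, offsets = offs,
    test_points = test_points,
    n_base_reactions = length(network$reactions))
  out
}

# Column index (within the register block) of register m+1 of point l.
register_column <- function(network, l, m) {
  a <- augmentation_info(network)
  if (is.null(a) || l > length(a$s_points)) stop("missing shift registers")
  if (m >= a$rho[l]) stop("register index exceeds rho for this point")
  network$d + a$offsets[l] + m + 1L
}

#' Empirical Erlang-lag sample for a register bank
#'
#' At any time the \eqn{(m+1)}-th register of point \eqn{\ell} holds
#' \eqn{X_n(T - \tau)} where \eqn{\tau} is the elapsed time since the
#' \eqn{(m+1)}-th most recent firing of the reset reaction, so \eqn{\tau}
#' is Erlang\eqn{(m+1, s_\ell)} distributed at stationarity.  This function
#' extracts the empirical lag sample from a recorded trajectory at a
#' uniform grid of probe times, for distributional testing.
#'
#' @param trajectory A `"ctmc_trajectory"` of an augmented network (with
#'   `which` recorded).
#' @param l Index of the finite interpolation point.
#' @param m Register order (`0 <= m < rho[l]`).
#' @param n_probe Number of uniform probe times on the second half of the
#'   horizon.
#' @return Numeric vector of lags.
#' @export
register_lags <- function(trajectory, l, m, n_probe = 1000) {
  net <- trajectory$network
  a <- augmentation_info(net)
  if (is.null(a)) stop("trajectory does not carry registers")
  k_reset <- a$n_base_reactions + l
  fire_times <- trajectory$times[which(trajectory$which == k_reset)]
  if (length(fire_times) < m + 1L)
    stop("insufficient firings of the reset reaction")
  probes <- seq(trajectory$Tf / 2, trajectory$Tf, length.out = n_probe)
  probes <- probes[probes > fire_times[m + 1L]]
  idx <- findInterval(probes, fire_times)
  keep <- idx >= m + 1L
  probes[keep] - fire_times[idx[keep] - m]
}
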