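# Independent truncated-generator oracle: enumerate a finite state space,
# build the dense generator matrix by explicit transition enumeration,
# extract the stationary vector from its null space, and compute the
# resolvent function and its derivatives by direct linear solves.  This
# shares no code path with the package's estimators beyond propensity().

truncated_generator <- function(network, states) {
  keys <- apply(states, 1L, paste, collapse = ",")
  ns <- nrow(states)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    x <- states[i, ]
    for (r in network$reactions) {
      lam <- propensity(r, x)
      if (lam <= 0) next
      xp <- x + r$displacement
      j <- match(paste(xp, collapse = ","), keys)
      if (!is.na(j)) {
        Q[i, j] <- Q[i, j] + lam
        Q[i, i] <- Q[i, i] - lam
      }
    }
  }
  Q
}

spectral_oracle <- function(network, states) {
  states <- as.matrix(states)
  Q <- truncated_generator(network, states)
  ev <- eigen(t(Q))
  k <- which.min(abs(ev$values))
  pi_vec <- Re(ev$vectors[, k])
  pi_vec <- pi_vec / sum(pi_vec)
  xn <- states[, network$output]
  mu <- sum(pi_vec * xn)
  f <- xn - mu
  I <- diag(ns <- nrow(states))
  list(
    Q = Q, pi = pi_vec, mean = mu, var = sum(pi_vec * f^2), f = f,
    G = function(s) {
      vapply(s, function(si)
        sum(pi_vec * f * solve(si * I - Q, f)), numeric(1))
    },
    D_inf = function(m) {
      v <- f
      if (m > 0) for (i in seq_len(m)) v <- as.numeric(Q %*% v)
      sum(pi_vec * f * v)
    },
    D_fin = function(s, m) {
      M <- s * I - Q
      v <- f
      for (i in seq_len(m + 1L)) v <- solve(M, v)
      (-1)^m * sum(pi_vec * f * v)
    })
}

# state spaces for the two oracle fixtures
bd_states <- function(cap = 30) matrix(0:cap, ncol = 1)
telegraph_states <- function() matrix(0:1, ncol = 1)

expect_within_3se <- function(est, se, truth, label = "") {
  expect_lt(abs(est - truth), 3 * se + 1e-12,
            label = paste0(label, " |", est, " - ", truth, "| vs 3*", se))
}
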