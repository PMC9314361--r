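# Vectorised evaluation of generator powers and covariate integrands over
# the ensemble's unique-state table.  For fixed-displacement networks,
# A^m f on the visited states only needs f on the m-jump neighbourhood, so
# we close the table under jumps once and evaluate level by level with
# vectorised propensities, instead of recursing per state.

state_keys <- function(S) {
  if (nrow(S) == 0) return(character(0))
  do.call(paste, c(as.data.frame(S), sep = ","))
}

# ns x K matrix of propensities over a state matrix (fixed displacements).
propensity_matrix <- function(network, S) {
  ns <- nrow(S)
  K <- length(network$reactions)
  L <- matrix(0, ns, K)
  for (k in seq_len(K)) {
    r <- network$reactions[[k]]
    p <- r$propensity
    L[, k] <- switch(p$type,
      mass_action = {
        a <- rep(p$rate, ns)
        for (j in seq_len(ncol(S))) {
          n <- r$reactants[j]
          if (n > 0) {
            xj <- S[, j]
            fac <- xj
            if (n > 1) for (t in seq_len(n - 1)) fac <- fac * (xj - t)
            a <- a * fac / factorial(n)
          }
        }
        pmax(a, 0)
      },
      const = rep(p$value, ns),
      affine = pmax(p$const + as.numeric(S %*% p$coef), 0),
      hill_repression = p$K0 / (p$K1 + S[, p$species]^p$H),
      hill_feedback = 4 * p$kfb * p$mu^2 / (p$mu + S[, p$species]),
      prop_feedback = p$kfb * pmax(3 * p$mu - S[, p$species], 0),
      stop("vectorised propensities require structured rate laws"))
  }
  L
}

# Closure of `states` under up to `depth` forward jumps, with neighbour
# index maps and A^j f values for j = 0..m_max.  Fixed displacements only.
amf_table <- function(network, states, m_max, center) {
  if (any(vapply(network$reactions, function(r) !is.null(r$kernel), TRUE)))
    stop("vectorised generator powers require fixed displacements")
  reg <- vapply(network$reactions,
                function(r) !is.null(attr(r, "register")), TRUE)
  rxn <- network$reactions[!reg]
  K <- length(rxn)
  S <- as.matrix(states)
  storage.mode(S) <- "double"
  keys <- state_keys(S)
  for (depth in seq_len(m_max)) {
    new <- do.call(rbind, lapply(rxn, function(r)
      sweep(S, 2L, -r$displacement)))
    nk <- state_keys(new)
    fresh <- !(nk %in% keys) & !duplicated(nk) &
      rowSums(new < 0) == 0
    if (!any(fresh)) break
    S <- rbind(S, new[fresh, , drop = FALSE])
    keys <- c(keys, nk[fresh])
  }
  net_flat <- network
  net_flat$reactions <- rxn
  lam <- propensity_matrix(net_flat, S)
  nb <- lapply(rxn, function(r)
    match(state_keys(sweep(S, 2L, -r$displacement)), keys))
  n_out <- network$output
  vals <- matrix(NA_real_, nrow(S), m_max + 1L)
  vals[, 1L] <- S[, n_out] - center
  if (m_max >= 1L) for (m in seq_len(m_max)) {
    acc <- rep(0, nrow(S))
    for (k in seq_len(K)) {
      vk <- vals[nb[[k]], m]
      dlt <- vk - vals[, m]
      term <- lam[, k] * dlt
      term[lam[, k] == 0] <- 0  # zero rate: neighbour value irrelevant
      acc <- acc + term
    }
    vals[, m + 1L] <- acc
  }
  list(S = S, keys = keys, lam = lam, nb = nb, vals = vals,
       idx = match(state_keys(as.matrix(states)), keys))
}

# gamma_{jl} on the original table states, vectorised.
gamma_vec <- function(tab, j, l, idx) {
  acc <- rep(0, length(idx))
  for (k in seq_along(tab$nb)) {
    nbk <- tab$nb[[k]][idx]
    dj <- tab$vals[nbk, j + 1L] - tab$vals[idx, j + 1L]
    dl <- tab$vals[nbk, l + 1L] - tab$vals[idx, l + 1L]
    term <- tab$lam[idx, k] * dj * dl
    term[tab$lam[idx, k] == 0] <- 0
    acc <- acc + term
  }
  acc
}

# Covariate integrand Psi_m on the original table states, vectorised.
psi_vec <- function(tab, m) {
  idx <- tab$idx
  r <- m %/% 2L
  acc <- rep(0, length(idx))
  v <- function(k) tab$vals[idx, k + 1L]
  if (m %% 2L == 0L) {
    acc <- acc + 0.5 * choose(m, r) * v(r)^2
    if (r >= 2L) for (k in seq_len(r - 1L))
      acc <- acc + choose(m, k) * v(k) * v(m - k)
    for (k in seq_len(r) - 1L)
      acc <- acc + choose(m - 1L, k) * gamma_vec(tab, k, m - 1L - k, idx)
  } else {
    if (r >= 1L) for (k in seq_len(r))
      acc <- acc + choose(m, k) * v(k) * v(m - k)
    if (r >= 1L) for (k in seq_len(r) - 1L)
      acc <- acc + choose(m - 1L, k) * gamma_vec(tab, k, m - 1L - k, idx)
    acc <- acc + 0.5 * choose(m - 1L, r) * gamma_vec(tab, r, r, idx)
  }
  -acc
}
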