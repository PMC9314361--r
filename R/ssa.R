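#' @useDynLib ctmcpsd, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- compilation of a network to the C++ engine ------------------------

# Propensity / displacement type codes shared with src/ssa.cpp
PROP_CODE <- c(mass_action = 0L, const = 1L, affine = 2L,
               hill_repression = 3L, hill_feedback = 4L, prop_feedback = 5L)

compile_network <- function(network) {
  d <- network$d
  ny <- n_y_registers(network)
  nz <- n_z_registers(network)
  Dtot <- d + ny + nz
  K <- length(network$reactions)
  prop_type <- integer(K)
  prop_params <- vector("list", K)
  disp_type <- integer(K)
  disp_params <- vector("list", K)
  nu <- matrix(0L, K, d)
  engine <- "cpp"
  for (k in seq_len(K)) {
    r <- network$reactions[[k]]
    p <- r$propensity
    nu[k, ] <- as.integer(r$reactants)
    if (p$type == "custom") { engine <- "r"; next }
    prop_type[k] <- PROP_CODE[[p$type]]
    prop_params[[k]] <- switch(p$type,
      mass_action = p$rate,
      const = p$value,
      affine = c(p$const, p$coef),
      hill_repression = c(p$K0, p$K1, p$H, p$species - 1L),
      hill_feedback = c(p$kfb, p$mu, p$species - 1L),
      prop_feedback = c(p$kfb, p$mu, p$species - 1L))
    if (!is.null(r$kernel)) {
      kern <- r$kernel
      if (kern$kind == "custom") { engine <- "r"; next }
      disp_type[k] <- if (kern$kind == "binomial_partition") 1L else 2L
      delta <- c(kernel_delta(kern, d), rep(0, ny + nz))
      disp_params[[k]] <- c(length(kern$partition_species),
                            kern$partition_species - 1L, delta)
    } else if (!is.null(attr(r, "register"))) {
      reg <- attr(r, "register")
      if (reg$type == "shift") {
        disp_type[k] <- 3L
        disp_params[[k]] <- c(d + reg$start - 1L, reg$len)
      } else {
        disp_type[k] <- 4L
        disp_params[[k]] <- d + ny + reg$idx - 1L
      }
    } else {
      disp_type[k] <- 0L
      disp_params[[k]] <- c(r$displacement, rep(0, ny + nz))
    }
  }
  list(d = d, Dtot = Dtot, ny = ny, nz = nz, engine = engine,
       prop_type = prop_type, prop_params = prop_params, nu = nu,
       disp_type = disp_type, disp_params = disp_params)
}

full_state0 <- function(network, state0 = NULL) {
  if (is.null(state0)) state0 <- network$state0
  ny <- n_y_registers(network); nz <- n_z_registers(network)
  # registers start at the initial output count; any initialisation bias
  # decays away well before the burn-in cut-off
  c(state0, rep(state0[network$output], ny + nz))
}

# Fixed rule deriving the per-trajectory seed from the ensemble base seed.
derive_seed <- function(base_seed, q) {
  as.integer((as.numeric(base_seed) + 104729 * as.numeric(q)) %% 2147483647)
}

# ---- single-trajectory simulation --------------------------------------

#' Simulate an exact SSA trajectory
#'
#' Runs Gillespie's stochastic simulation algorithm for the (possibly
#' augmented) network over `[0, Tf]`, returning the full jump-time/state
#' path.  Reactions with a jump kernel draw their displacement from the
#' kernel; register reset reactions apply their reset map.  If all
#' propensities vanish the state is absorbing and the path is padded to the
#' horizon.
#'
#' @param network A [reaction_network()] (optionally [augment()]ed).
#' @param Tf Final time.
#' @param seed Integer RNG seed; identical seeds give identical paths.
#' @param state0 Initial state (base species only); defaults to the
#'   network's `state0`.
#' @param max_events Safety cap on the number of jumps.
#' @return A `"ctmc_trajectory"`: list with `times` (strictly increasing,
#'   starting at 0), `states` (one row per epoch, base species then any
#'   registers), `which` (index of the firing reaction, `NA` for the initial
#'   row) and `seed`.
#' @export
ssa_simulate <- function(network, Tf, seed, state0 = NULL, max_events = 5e7) {
  x0 <- full_state0(network, state0)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  comp <- compile_network(network)
  set.seed(seed)
  if (comp$engine == "cpp") {
    res <- ssa_run_cpp(x0, comp$d, network$output - 1L,
                       comp$prop_type, comp$prop_params, comp$nu,
                       comp$disp_type, comp$disp_params,
                       Tf, 0, 1L, 0, TRUE, FALSE, max_events)
    times <- res$times; states <- res$states; which <- res$which
  } else {
    res <- ssa_run_r(network, x0, Tf, max_events)
    times <- res$times; states <- res$states; which <- res$which
  }
  colnames(states) <- state_names(network)
  structure(list(times = times, states = states, which = which,
                 seed = seed, network = network, Tf = Tf),
            class = "ctmc_trajectory")
}

state_names <- function(network) {
  ny <- n_y_registers(network); nz <- n_z_registers(network)
  c(network$species,
    if (ny > 0) paste0("Y", seq_len(ny)),
    if (nz > 0) paste0("Z", seq_len(nz)))
}

# Pure-R event loop: slow path for custom propensities / kernels.
ssa_run_r <- function(network, x0, Tf, max_events = 5e7) {
  d <- network$d
  x <- x0[seq_len(d)]
  reg <- x0[-seq_len(d)]
  t <- 0
  times <- numeric(0); states <- list(); whichv <- integer(0)
  times[1] <- 0; states[[1]] <- c(x, reg); whichv[1] <- NA_integer_
  i <- 1L
  repeat {
    a <- vapply(network$reactions, function(r) {
      lam <- propensity(r, x)
      if (!is.null(attr(r, "register"))) lam <- attr(r, "register")$rate
      lam
    }, numeric(1))
    a0 <- sum(a)
    if (a0 <= 0 || t >= Tf) break
    t <- t + stats::rexp(1, a0)
    if (t >= Tf) break
    k <- sample.int(length(a), 1L, prob = a)
    r <- network$reactions[[k]]
    regmeta <- attr(r, "register")
    if (!is.null(regmeta)) {
      if (regmeta$type == "shift") {
        idx <- regmeta$start + seq_len(regmeta$len) - 1L
        reg[idx] <- c(x[network$output], reg[idx[-length(idx)]])
      } else {
        reg[n_y_registers(network) + regmeta$idx] <- x[network$output]
      }
    } else if (!is.null(r$kernel)) {
      x <- sample_kernel(r$kernel, x)
    } else {
      x <- x + r$displacement
    }
    i <- i + 1L
    if (i > max_events) stop("simulation exceeded max_events")
    times[i] <- t; states[[i]] <- c(x, reg); whichv[i] <- k
  }
  list(times = times, states = do.call(rbind, states), which = whichv)
}

sample_kernel <- function(kernel, state) {
  d <- length(state)
  x <- state
  switch(kernel$kind,
    binomial_partition = {
      idx <- kernel$partition_species
      x[idx] <- stats::rbinom(length(idx), state[idx], 0.5)
      x + kernel_delta(kernel, d)
    },
    strict_binary_partition = {
      idx <- kernel$partition_species
      odd <- state[idx] %% 2 == 1
      x[idx] <- floor(state[idx] / 2) +
        ifelse(odd, stats::rbinom(length(idx), 1, 0.5), 0)
      x + kernel_delta(kernel, d)
    },
    custom = kernel$sample(state),
    stop("unsupported kernel kind"))
}

#' @export
print.ctmc_trajectory <- function(x, ...) {
  cat("<ctmc_trajectory> ", length(x$times), " epochs on [0, ",
      format(x$Tf), "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.ctmc_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Tidy a trajectory into a tibble
#' @param x A `"ctmc_trajectory"`.
#' @param ... Unused.
#' @export
tidy.ctmc_trajectory <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Write / read a trajectory as CSV
#'
#' Columns: `time`, then one column per species (and register, if the
#' network was augmented).  The reader re-attaches a network so that path
#' functionals keep working.
#'
#' @param trajectory A `"ctmc_trajectory"`.
#' @param path File path.
#' @param network The network the trajectory belongs to.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  # sentinel row carrying the horizon (the path is constant after the
  # last jump, so repeating the final state loses nothing)
  df <- rbind(df, utils::tail(df, 1))
  df$time[nrow(df)] <- trajectory$Tf
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, network) {
  df <- utils::read.csv(path, check.names = FALSE)
  states <- as.matrix(df[, -1, drop = FALSE])
  structure(list(times = df$time, states = states,
                 which = rep(NA_integer_, nrow(df)), seed = NA_integer_,
                 network = network, Tf = max(df$time)),
            class = "ctmc_trajectory")
}

# ---- path functionals ---------------------------------------------------

#' Exact time average of a state functional along a trajectory
#'
#' Computes \eqn{(T_f - T_c)^{-1}\int_{T_c}^{T_f} g(X(t))\,dt} exactly from
#' the piecewise-constant path (sum of `g(state) * holding-time`); no
#' discretisation is involved.
#'
#' @param trajectory A `"ctmc_trajectory"`.
#' @param g Function `state -> numeric(1)` (receives the full state row).
#' @param Tc,Tf Averaging window; must satisfy `Tc < Tf <= horizon`.
#' @export
time_average <- function(trajectory, g, Tc = 0, Tf = NULL) {
  if (is.null(Tf)) Tf <- trajectory$Tf
  if (Tc >= Tf) stop("empty averaging interval (Tc >= Tf)")
  if (Tf > trajectory$Tf + 1e-12) stop("Tf exceeds the simulated horizon")
  times <- c(trajectory$times, trajectory$Tf)
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    lo <- max(times[i], Tc); hi <- min(times[i + 1L], Tf)
    if (hi > lo) total <- total + g(trajectory$states[i, ]) * (hi - lo)
  }
  unname(total / (Tf - Tc))
}

# ---- ensembles ----------------------------------------------------------

#' Simulate an ensemble of trajectories with exact path accumulators
#'
#' Runs `Q` independent SSA trajectories (per-trajectory seeds derived from
#' `seed` by a fixed splitting rule) and returns, per trajectory, the exact
#' integrals over `[Tc, Tf]` needed by the moment and spectral estimators:
#' \eqn{\int x_n}, \eqn{\int x_n^2}, the squared register-output gaps
#' \eqn{\int (Y_j - x_n)^2} and \eqn{\int (Z_r - x_n)^2}, and (optionally)
#' the table of visited base states with occupation times, used to evaluate
#' generator-based integrands once per unique state.  When `Q = 1` the
#' window is split into `n_batch` equal batches so that standard errors can
#' still be formed.
#'
#' @param network A (possibly augmented) [reaction_network()].
#' @param Q Number of trajectories.
#' @param Tf,Tc Horizon and burn-in cut-off, `0 <= Tc < Tf`.
#' @param seed Base seed.
#' @param record_table Keep the unique-state occupation table.
#' @param sample_dt If positive, also record uniform samples of the base
#'   species every `sample_dt` time units on `[Tc, Tf]`.
#' @param state0 Initial base state.
#' @param n_batch Number of within-path batches when `Q = 1`.
#' @return A `"ctmc_ensemble"` object.
#' @export
ssa_ensemble <- function(network, Q = 10, Tf = 1e4, Tc = 1e2, seed = 1,
                         record_table = FALSE, sample_dt = 0,
                         state0 = NULL, n_batch = 20, max_events = 5e8) {
  stopifnot(Q >= 1, Tc >= 0, Tc < Tf)
  comp <- compile_network(network)
  if (comp$engine != "cpp")
    stop("ssa_ensemble requires structured propensities (no custom closures)")
  x0 <- full_state0(network, state0)
  nb <- if (Q == 1L) as.integer(n_batch) else 1L
  runs <- vector("list", Q)
  for (q in seq_len(Q)) {
    set.seed(derive_seed(seed, q))
    runs[[q]] <- ssa_run_cpp(x0, comp$d, network$output - 1L,
                             comp$prop_type, comp$prop_params, comp$nu,
                             comp$disp_type, comp$disp_params,
                             Tf, Tc, nb, sample_dt,
                             FALSE, record_table, max_events)
  }
  structure(list(runs = runs, network = network, Q = Q, Tf = Tf, Tc = Tc,
                 seed = seed, n_batch = nb, sample_dt = sample_dt),
            class = "ctmc_ensemble")
}

#' @export
print.ctmc_ensemble <- function(x, ...) {
  cat("<ctmc_ensemble> Q = ", x$Q, ", window [", format(x$Tc), ", ",
      format(x$Tf), "], seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Flatten the per-run, per-batch accumulators into batch vectors/matrices.
ensemble_batches <- function(ens) {
  t_eff <- unlist(lapply(ens$runs, function(r) r$t_eff))
  int_x <- unlist(lapply(ens$runs, function(r) r$int_x))
  int_x2 <- unlist(lapply(ens$runs, function(r) r$int_x2))
  int_reg <- do.call(rbind, lapply(ens$runs, function(r) r$int_reg))
  list(t_eff = t_eff, int_x = int_x, int_x2 = int_x2, int_reg = int_reg)
}

#' Pooled stationary mean and variance of the output species
#'
#' Pooled time-average estimators of the stationary mean and variance of
#' the output copy-number: the variance is the pooled second moment minus
#' the squared pooled mean, computed from exact path integrals.  Standard
#' errors come from the spread of per-trajectory (or per-batch) estimates.
#'
#' @param ensemble A `"ctmc_ensemble"` (or a list of `"ctmc_trajectory"`
#'   objects, in which case `Tc`/`Tf` must be supplied).
#' @param Tc,Tf Optional window override for trajectory lists.
#' @return A list with `mean`, `variance`, `mean_se`, `variance_se` and the
#'   per-batch values.
#' @export
stationary_mean_variance <- function(ensemble, Tc = NULL, Tf = NULL) {
  if (inherits(ensemble, "ctmc_trajectory")) ensemble <- list(ensemble)
  if (is.list(ensemble) && !inherits(ensemble, "ctmc_ensemble")) {
    trajs <- ensemble
    if (is.null(Tf)) Tf <- trajs[[1]]$Tf
    if (is.null(Tc)) Tc <- 0
    if (Tc >= Tf) stop("Tc must be < Tf")
    n <- trajs[[1]]$network$output
    m1 <- vapply(trajs, time_average, numeric(1),
                 g = function(s) s[n], Tc = Tc, Tf = Tf)
    m2 <- vapply(trajs, time_average, numeric(1),
                 g = function(s) s[n]^2, Tc = Tc, Tf = Tf)
    mean_hat <- mean(m1)
    var_hat <- mean(m2) - mean_hat^2
    Q <- length(trajs)
    vb <- m2 - m1^2
    return(list(mean = mean_hat, variance = var_hat,
                mean_se = stats::sd(m1) / sqrt(Q),
                variance_se = if (Q > 1) stats::sd(vb) / sqrt(Q) else NA_real_,
                batch_mean = m1, batch_variance = vb))
  }
  b <- ensemble_batches(ensemble)
  mean_hat <- sum(b$int_x) / sum(b$t_eff)
  second <- sum(b$int_x2) / sum(b$t_eff)
  var_hat <- second - mean_hat^2
  bm <- b$int_x / b$t_eff
  bv <- b$int_x2 / b$t_eff - bm^2
  B <- length(bm)
  list(mean = mean_hat, variance = var_hat,
       mean_se = stats::sd(bm) / sqrt(B),
       variance_se = stats::sd(bv) / sqrt(B),
       batch_mean = bm, batch_variance = bv)
}

# Merge the per-run unique-state tables into one states matrix + per-batch
# weight matrix (batches in the same order as ensemble_batches()).
ensemble_state_table <- function(ens) {
  if (is.null(ens$runs[[1]]$table_states))
    stop("ensemble was simulated without record_table = TRUE")
  keys <- character(0)
  stmap <- new.env(parent = emptyenv(), hash = TRUE)
  Q <- ens$Q; nb <- ens$n_batch
  B <- Q * nb
  rows <- list(); wlist <- list()
  for (q in seq_len(Q)) {
    st <- ens$runs[[q]]$table_states
    wt <- ens$runs[[q]]$table_weights
    k <- apply(st, 1L, paste0, collapse = ",")
    rows[[q]] <- st; wlist[[q]] <- wt
    keys <- c(keys, k)
  }
  allst <- do.call(rbind, rows)
  ukeys <- unique(keys)
  idx <- match(keys, ukeys)
  W <- matrix(0, length(ukeys), B)
  off <- 0L; roff <- 0L
  for (q in seq_len(Q)) {
    nr <- nrow(wlist[[q]])
    ii <- idx[roff + seq_len(nr)]
    for (bcol in seq_len(nb)) {
      agg <- rowsum(wlist[[q]][, bcol, drop = FALSE], group = ii)
      W[as.integer(rownames(agg)), off + bcol] <-
        W[as.integer(rownames(agg)), off + bcol] + agg[, 1L]
    }
    off <- off + nb; roff <- roff + nr
  }
  states <- allst[match(ukeys, keys), , drop = FALSE]
  list(states = states, weights = W)
}
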