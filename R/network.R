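#' Propensity functions
#'
#' Constructors for the propensity (instantaneous firing rate) of a reaction.
#' `mass_action()` follows the classical combinatorial law
#' \eqn{\lambda(x) = \theta \prod_j \binom{x_j}{\nu_j}} where \eqn{\nu_j} is
#' the number of molecules of species \eqn{j} consumed.  The remaining
#' constructors cover the structured rate laws used by the example networks:
#' clamped affine rates \eqn{\max(c_0 + w^T x, 0)} (linearised repression is
#' simulated with its positive part), repressing Hill functions
#' \eqn{K_0/(K_1 + x_j^H)}, the Hill-type feedback \eqn{4 k_{fb}\mu^2/(\mu +
#' x_j)} and its proportional linearisation \eqn{k_{fb}\max(3\mu - x_j, 0)}.
#' `custom_propensity()` wraps an arbitrary non-negative function of the
#' state (values are clamped at 0); networks containing one are simulated
#' with the slower pure-R event loop.
#'
#' @param rate,value Positive rate constant / constant rate.
#' @param const,coef Intercept and coefficient vector (length d) of an
#'   affine rate, clamped at zero during simulation.
#' @param K0,K1,H Hill parameters; `H > 0` is the cooperativity.
#' @param species Index (1-based) of the regulating species.
#' @param kfb,mu Feedback gain and reference copy-number.
#' @param fn Function `state -> rate`; negative values are clamped to 0.
#' @return An object of class `"propensity"`.
#' @name propensities
NULL

new_propensity <- function(type, ...) {
  structure(list(type = type, ...), class = "propensity")
}

#' @rdname propensities
#' @export
mass_action <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  new_propensity("mass_action", rate = rate)
}

#' @rdname propensities
#' @export
const_propensity <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  new_propensity("const", value = value)
}

#' @rdname propensities
#' @export
affine_propensity <- function(const, coef) {
  stopifnot(is.numeric(const), length(const) == 1L, is.numeric(coef))
  new_propensity("affine", const = const, coef = as.numeric(coef))
}

#' @rdname propensities
#' @export
hill_repression <- function(K0, K1, H, species) {
  stopifnot(K0 > 0, K1 > 0, H > 0, species >= 1)
  new_propensity("hill_repression", K0 = K0, K1 = K1, H = H,
                 species = as.integer(species))
}

#' @rdname propensities
#' @export
hill_feedback <- function(kfb, mu, species) {
  stopifnot(kfb >= 0, mu > 0)
  new_propensity("hill_feedback", kfb = kfb, mu = mu,
                 species = as.integer(species))
}

#' @rdname propensities
#' @export
proportional_feedback <- function(kfb, mu, species) {
  stopifnot(kfb >= 0, mu > 0)
  new_propensity("prop_feedback", kfb = kfb, mu = mu,
                 species = as.integer(species))
}

#' @rdname propensities
#' @export
custom_propensity <- function(fn) {
  stopifnot(is.function(fn))
  new_propensity("custom", fn = fn)
}

#' Jump kernels for state-dependent random displacements
#'
#' When a reaction fires, the default behaviour is a fixed integer
#' displacement of the state.  A jump kernel instead draws the post-jump
#' state at random, which is how whole-cell events such as division-time
#' molecule partitioning are modelled.  `binomial_partition_kernel()` sends
#' each molecule of the listed species independently to the tracked daughter
#' cell with probability 1/2 (post-state mean is `state/2`, variance
#' `state/4` componentwise); `strict_binary_kernel()` gives the tracked cell
#' exactly half of each species, an odd count `2m + 1` becoming `m` or
#' `m + 1` with probability 1/2 each.  Both kernels expose closed-form first
#' and second conditional moments so that generator calculations on affine
#' functions remain exact without enumerating the partition support.
#' `delta` is an additional fixed displacement applied after partitioning
#' (used, e.g., to reset a cell-cycle stage indicator).
#'
#' @param partition_species Indices of the species to partition.
#' @param delta Fixed displacement (length d) applied after partitioning.
#' @param sample,mean,cov_diag For `custom_kernel()`: a sampler
#'   `state -> post-state`, the conditional mean map, and the diagonal of
#'   the conditional covariance (components assumed independent).
#' @return An object of class `"jump_kernel"`.
#' @name jump_kernels
NULL

new_kernel <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "jump_kernel")
}

#' @rdname jump_kernels
#' @export
binomial_partition_kernel <- function(partition_species, delta = NULL) {
  new_kernel("binomial_partition",
             partition_species = as.integer(partition_species),
             delta = delta)
}

#' @rdname jump_kernels
#' @export
strict_binary_kernel <- function(partition_species, delta = NULL) {
  new_kernel("strict_binary_partition",
             partition_species = as.integer(partition_species),
             delta = delta)
}

#' @rdname jump_kernels
#' @export
custom_kernel <- function(sample, mean, cov_diag) {
  stopifnot(is.function(sample), is.function(mean), is.function(cov_diag))
  new_kernel("custom", sample = sample, mean = mean, cov_diag = cov_diag)
}

kernel_delta <- function(kernel, d) {
  if (is.null(kernel$delta)) rep(0, d) else kernel$delta
}

#' Conditional post-jump mean of a kernel
#' @param kernel A `jump_kernel`.
#' @param state Non-negative integer state vector.
#' @return `E[x' | x]`, the expected post-jump state.
#' @export
kernel_mean <- function(kernel, state) {
  switch(kernel$kind,
    binomial_partition = ,
    strict_binary_partition = {
      m <- state
      m[kernel$partition_species] <- state[kernel$partition_species] / 2
      m + kernel_delta(kernel, length(state))
    },
    custom = kernel$mean(state),
    stop("unsupported kernel kind: ", kernel$kind)
  )
}

#' Conditional post-jump variance (diagonal) of a kernel
#' @inheritParams kernel_mean
#' @return Componentwise conditional variance of the post-jump state.
#' @export
kernel_cov_diag <- function(kernel, state) {
  v <- rep(0, length(state))
  switch(kernel$kind,
    binomial_partition = {
      v[kernel$partition_species] <- state[kernel$partition_species] / 4
      v
    },
    strict_binary_partition = {
      # exactly half, randomised floor/ceil for odd counts: variance 1/4
      idx <- kernel$partition_species
      v[idx] <- ifelse(state[idx] %% 2 == 1, 0.25, 0)
      v
    },
    custom = kernel$cov_diag(state),
    stop("unsupported kernel kind: ", kernel$kind)
  )
}

#' Define a reaction
#'
#' A reaction consumes `reactants` (a non-negative integer vector over all
#' species, the mass-action order), fires with the given `propensity`, and
#' displaces the state either by the fixed stoichiometric change
#' `products - reactants` (or an explicit `displacement`) or by drawing from
#' a `kernel`.
#'
#' @param reactants Integer vector of molecules consumed, length d.
#' @param products Integer vector of molecules produced, length d (ignored
#'   when `displacement` or `kernel` is given).
#' @param propensity A `"propensity"` object.
#' @param displacement Optional explicit integer displacement vector.
#' @param kernel Optional `"jump_kernel"`.
#' @param name Optional reaction label used in error messages.
#' @return An object of class `"reaction"`.
#' @export
reaction <- function(reactants, products = NULL, propensity,
                     displacement = NULL, kernel = NULL, name = NULL) {
  stopifnot(inherits(propensity, "propensity"))
  reactants <- as.numeric(reactants)
  if (any(reactants < 0) || any(reactants != round(reactants)))
    stop("reactant counts must be non-negative integers")
  if (!is.null(kernel)) {
    stopifnot(inherits(kernel, "jump_kernel"))
    disp <- NULL
  } else if (!is.null(displacement)) {
    disp <- as.numeric(displacement)
    if (length(disp) != length(reactants)) stop("displacement length mismatch")
  } else {
    if (is.null(products)) stop("supply products, displacement or kernel")
    products <- as.numeric(products)
    if (length(products) != length(reactants)) stop("products length mismatch")
    disp <- products - reactants
  }
  structure(list(reactants = reactants, displacement = disp,
                 kernel = kernel, propensity = propensity, name = name),
            class = "reaction")
}

#' Define a reaction network
#'
#' The central model object: a continuous-time Markov chain on the
#' non-negative integer lattice whose components are the copy-numbers of the
#' named species.  One species is designated the *output*; all spectral
#' quantities refer to its trajectory.
#'
#' @param species Character vector of species names (length d >= 1).
#' @param reactions List of [reaction()] objects whose vectors have length d.
#' @param output Output species: name or index.
#' @param state0 Default initial state (non-negative integers); defaults to
#'   zeros.
#' @return An object of class `"reaction_network"`.
#' @export
reaction_network <- function(species, reactions, output, state0 = NULL) {
  species <- as.character(species)
  d <- length(species)
  stopifnot(d >= 1, length(reactions) >= 1)
  for (r in reactions) {
    if (!inherits(r, "reaction")) stop("reactions must be reaction() objects")
    if (length(r$reactants) != d) stop("reaction vector length != d")
  }
  if (is.character(output)) output <- match(output, species)
  output <- as.integer(output)
  if (is.na(output) || output < 1L || output > d)
    stop("output species not found")
  if (is.null(state0)) state0 <- rep(0, d)
  stopifnot(length(state0) == d, all(state0 >= 0))
  structure(list(species = species, reactions = reactions, d = d,
                 output = output, state0 = as.numeric(state0)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$d, " species, ", length(x$reactions),
      " reactions; output: ", x$species[x$output], "\n", sep = "")
  invisible(x)
}

#' Evaluate a reaction propensity at a state
#'
#' @param reaction A [reaction()] object.
#' @param state Non-negative integer state vector.
#' @return The non-negative firing rate \eqn{\lambda_k(x)}.
#' @export
propensity <- function(reaction, state) {
  if (any(state < 0)) stop("state must be componentwise non-negative")
  p <- reaction$propensity
  switch(p$type,
    mass_action = {
      a <- p$rate
      nu <- reaction$reactants
      for (j in seq_along(state)) {
        n <- nu[j]
        if (n > 0) {
          if (state[j] < n) return(0)
          a <- a * prod(state[j] - seq_len(n) + 1) / factorial(n)
        }
      }
      a
    },
    const = p$value,
    affine = max(p$const + sum(p$coef * state), 0),
    hill_repression = p$K0 / (p$K1 + state[p$species]^p$H),
    hill_feedback = 4 * p$kfb * p$mu^2 / (p$mu + state[p$species]),
    prop_feedback = p$kfb * max(3 * p$mu - state[p$species], 0),
    custom = max(p$fn(state), 0),
    stop("unknown propensity type")
  )
}

all_propensities <- function(network, state) {
  vapply(network$reactions, propensity, numeric(1), state = state)
}
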