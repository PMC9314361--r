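# Programmatic constructors for the example networks.  The linear-network
# parameter sets (gene expression, telegraph/RNA splicing, IFF, NFB) are
# the module's reference fixtures: their analytic PSDs have simple closed
# forms that the unit suite pins down coefficient by coefficient.  The
# nonlinear fixtures (repressilator, AIF-controlled gene expression,
# self-regulating gene, cell-cycle host) use representative defaults chosen
# to sit in the qualitative regime of interest (oscillatory, adapting,
# etc.); they back property-based tests rather than numeric reproduction.

#' Example network catalog
#'
#' `make_network(name, ...)` builds any catalog network by name with
#' optional parameter overrides; `list_fixtures()` names them all.
#'
#' @param name Catalog name, one of `list_fixtures()`.
#' @param ... Parameters forwarded to the constructor.
#' @export
make_network <- function(name, ...) {
  ctors <- fixture_catalog()
  if (!name %in% names(ctors))
    stop("unknown network '", name, "'; available: ",
         paste(names(ctors), collapse = ", "))
  ctors[[name]](...)
}

#' @rdname make_network
#' @export
list_fixtures <- function() names(fixture_catalog())

fixture_catalog <- function() {
  list(birth_death = birth_death,
       telegraph = telegraph,
       gene_expression = gene_expression,
       rna_splicing = rna_splicing,
       iff = iff_network,
       nfb = nfb_network,
       feedback_gene_expression = feedback_gene_expression,
       self_regulating_gene = self_regulating_gene,
       repressilator = repressilator,
       aif_gene_expression = aif_gene_expression,
       cell_cycle_host = cell_cycle_host)
}

unit <- function(d, j) { v <- rep(0, d); v[j] <- 1; v }

#' Birth-death network (constitutive transcription)
#'
#' `0 -> X` at rate `k`, `X -> 0` at rate `gamma`.  Stationary law
#' Poisson(`k/gamma`); PSD \eqn{2k/(\gamma^2 + \omega^2)}.
#'
#' @param k,gamma Production and degradation rate constants.
#' @export
birth_death <- function(k = 1, gamma = 1) {
  reaction_network(
    species = "X",
    reactions = list(
      reaction(0, 1, mass_action(k), name = "birth"),
      reaction(1, 0, mass_action(gamma), name = "death")),
    output = "X",
    state0 = round(k / gamma))
}

#' Two-state telegraph (gene switching) network
#'
#' A single gene copy switching between active (`G = 1`) and inactive
#' (`G = 0`): activation at rate `k_on (1 - G)`, deactivation at
#' `k_off G`.  PSD of the active-state indicator:
#' \eqn{2 k_{on} k_{off} / [(k_{on}+k_{off})((k_{on}+k_{off})^2 +
#' \omega^2)]}.
#'
#' @param k_on,k_off Switching rates.
#' @export
telegraph <- function(k_on = 1, k_off = 3) {
  reaction_network(
    species = "G",
    reactions = list(
      reaction(0, 0, affine_propensity(k_on, -k_on), displacement = 1,
               name = "activate"),
      reaction(1, 0, mass_action(k_off), name = "deactivate")),
    output = "G",
    state0 = 0)
}

#' Two-stage gene expression network
#'
#' Constitutive transcription of mRNA (`X1`) at rate `k_r`, translation
#' `X1 -> X1 + X2` at `k_p`, first-order decay of both species.  Output:
#' protein `X2`.
#'
#' @param k_r,gamma_r mRNA production and decay rates.
#' @param k_p,gamma_p Protein production and decay rates.
#' @export
gene_expression <- function(k_r = 10, gamma_r = 1, k_p = 2, gamma_p = 0.5) {
  reaction_network(
    species = c("mRNA", "protein"),
    reactions = list(
      reaction(c(0, 0), c(1, 0), mass_action(k_r), name = "transcription"),
      reaction(c(1, 0), c(0, 0), mass_action(gamma_r), name = "mRNA_decay"),
      reaction(c(1, 0), c(1, 1), mass_action(k_p), name = "translation"),
      reaction(c(0, 1), c(0, 0), mass_action(gamma_p), name = "protein_decay")),
    output = "protein",
    state0 = round(c(k_r / gamma_r, k_r * k_p / (gamma_r * gamma_p))))
}

#' RNA splicing network
#'
#' A gene switches between active (`G = 1`, transcription rate `alpha_on`)
#' and inactive (`G = 0`, rate `alpha_off`) states; transcription creates
#' unspliced mRNA (`U`) which is spliced (`U -> S`) at rate `beta`; both
#' mRNA forms decay.  Output: spliced mRNA `S`.
#'
#' @param k_on,k_off Gene switching rates.
#' @param alpha_on,alpha_off Transcription rates in the two gene states.
#' @param beta Splicing rate.
#' @param gamma_u,gamma_r Unspliced / spliced decay rates.
#' @export
rna_splicing <- function(k_on = 1, k_off = 3, alpha_on = 6, alpha_off = 0.4,
                         beta = 1, gamma_u = 2, gamma_r = 0.5) {
  gbar <- k_on / (k_on + k_off)
  ubar <- (alpha_off + (alpha_on - alpha_off) * gbar) / (beta + gamma_u)
  reaction_network(
    species = c("G", "U", "S"),
    reactions = list(
      reaction(c(0, 0, 0), c(0, 0, 0),
               affine_propensity(k_on, c(-k_on, 0, 0)),
               displacement = c(1, 0, 0), name = "activate"),
      reaction(c(1, 0, 0), c(0, 0, 0), mass_action(k_off),
               name = "deactivate"),
      reaction(c(0, 0, 0), c(0, 1, 0),
               affine_propensity(alpha_off, c(alpha_on - alpha_off, 0, 0)),
               name = "transcription"),
      reaction(c(0, 1, 0), c(0, 0, 1), mass_action(beta), name = "splicing"),
      reaction(c(0, 1, 0), c(0, 0, 0), mass_action(gamma_u), name = "U_decay"),
      reaction(c(0, 0, 1), c(0, 0, 0), mass_action(gamma_r), name = "S_decay")),
    output = "S",
    state0 = round(c(gbar, ubar, beta * ubar / gamma_r)))
}

#' Incoherent feedforward (IFF) network
#'
#' Input at constant level `I0` produces the controller `C` (rate
#' `k_c I0`) and the output `O` (rate `k_o I0`); `C` represses `O`
#' production through the linearised feedforward function
#' \eqn{F_f(x_c) = \beta_0 - \beta_{ff} x_c} (simulated as its positive
#' part).  The output PSD is monotonically decreasing: the IFF topology
#' cannot oscillate.
#'
#' @param I0 Input abundance.
#' @param k_c,gamma_c Controller production / decay.
#' @param k_o,gamma_o Output production / decay.
#' @param beta_0,beta_ff Basal rate and feedforward strength.
#' @export
iff_network <- function(I0 = 10, k_c = 3.6, gamma_c = 1, k_o = 5,
                        beta_0 = 15, beta_ff = 0.5, gamma_o = 0.5) {
  cbar <- k_c * I0 / gamma_c
  obar <- (k_o * I0 + beta_0 - beta_ff * cbar) / gamma_o
  reaction_network(
    species = c("C", "O"),
    reactions = list(
      reaction(c(0, 0), c(1, 0), mass_action(k_c * I0), name = "C_production"),
      reaction(c(1, 0), c(0, 0), mass_action(gamma_c), name = "C_decay"),
      reaction(c(0, 0), c(0, 0),
               affine_propensity(k_o * I0 + beta_0, c(-beta_ff, 0)),
               displacement = c(0, 1), name = "O_production"),
      reaction(c(0, 1), c(0, 0), mass_action(gamma_o), name = "O_decay")),
    output = "O",
    state0 = round(c(cbar, obar)))
}

#' Negative feedback (NFB) network
#'
#' Input at level `I0` produces the controller `C` at rate
#' \eqn{I_0 F_b(x_o)} with the linearised feedback \eqn{F_b(x_o) = \beta_0
#' - \beta_{fb} x_o} (positive part in simulation); `C` produces the
#' output `O` at rate `k_o x_c`; both species decay.  For sufficiently
#' strong feedback drive the output PSD peaks at a positive frequency.
#'
#' @param I0 Input abundance.
#' @param beta_0,beta_fb Basal production rate and feedback strength.
#' @param k_o Output production rate constant.
#' @param gamma_c,gamma_o Decay rates.
#' @export
nfb_network <- function(I0 = 10, beta_0 = 5, beta_fb = 0.05, k_o = 2,
                        gamma_c = 1, gamma_o = 0.5) {
  den <- gamma_c * gamma_o + k_o * beta_fb * I0
  cbar <- gamma_o * beta_0 * I0 / den
  obar <- k_o * beta_0 * I0 / den
  reaction_network(
    species = c("C", "O"),
    reactions = list(
      reaction(c(0, 0), c(0, 0),
               affine_propensity(I0 * beta_0, c(0, -I0 * beta_fb)),
               displacement = c(1, 0), name = "C_production"),
      reaction(c(1, 0), c(0, 0), mass_action(gamma_c), name = "C_decay"),
      reaction(c(1, 0), c(1, 1), mass_action(k_o), name = "O_production"),
      reaction(c(0, 1), c(0, 0), mass_action(gamma_o), name = "O_decay")),
    output = "O",
    state0 = round(c(cbar, obar)))
}

#' Gene expression with linear transcriptional feedback
#'
#' The downstream circuit of the entrainment study: transcription at rate
#' \eqn{k_r + c_{in} - k_{fb} x_2} (positive part), translation and decay
#' as in [gene_expression()].  `input_const` is the frozen contribution
#' \eqn{\theta \bar p} of an upstream activator, used when applying the
#' PSD decomposition.
#'
#' @param k_r Basal transcription rate.
#' @param k_fb Feedback strength.
#' @param k_p,gamma_r,gamma_p Translation and decay rates.
#' @param input_const Constant transcription input (frozen upstream drive).
#' @export
feedback_gene_expression <- function(k_r = 50, k_fb = 0.5, k_p = 2,
                                     gamma_r = 1, gamma_p = 0.5,
                                     input_const = 0) {
  den <- gamma_r * gamma_p + k_p * k_fb
  x2bar <- k_p * (k_r + input_const) / den
  x1bar <- gamma_p * x2bar / k_p
  reaction_network(
    species = c("mRNA", "protein"),
    reactions = list(
      reaction(c(0, 0), c(0, 0),
               affine_propensity(k_r + input_const, c(0, -k_fb)),
               displacement = c(1, 0), name = "transcription"),
      reaction(c(1, 0), c(0, 0), mass_action(gamma_r), name = "mRNA_decay"),
      reaction(c(1, 0), c(1, 1), mass_action(k_p), name = "translation"),
      reaction(c(0, 1), c(0, 0), mass_action(gamma_p), name = "protein_decay")),
    output = "protein",
    state0 = round(c(x1bar, x2bar)))
}

#' Self-regulating gene
#'
#' A birth-death process whose production rate is the repressing Hill
#' function \eqn{\lambda_H(x) = K_0/(K_1 + x^H)} of its own copy-number;
#' degradation is first-order.  The cooperativity `H` shapes the
#' normalised PSD, which is the basis of the spectral inference example.
#'
#' @param K0,K1,H Hill parameters.
#' @param gamma Degradation rate.
#' @export
self_regulating_gene <- function(K0 = 200, K1 = 10, H = 1, gamma = 1) {
  f <- function(x) K0 / (K1 + x^H) - gamma * x
  xbar <- stats::uniroot(f, c(0, K0 / gamma + 1))$root
  reaction_network(
    species = "X",
    reactions = list(
      reaction(0, 1, hill_repression(K0, K1, H, 1), name = "production"),
      reaction(1, 0, mass_action(gamma), name = "degradation")),
    output = "X",
    state0 = round(xbar))
}

#' Repressilator
#'
#' Three repressor proteins (TetR, cI, LacI) in a cyclic repression ring:
#' production of each protein follows the repressing Hill function
#' \eqn{K_0/(K_1 + x^H)} of its upstream repressor, with first-order
#' decay.  With `sponge = TRUE`, a sponge plasmid species competitively
#' binds free TetR (raising the derepression threshold of the cI gene):
#' `TetR + Sp <-> C` with rates `k_bind`, `k_unbind` and `sponge_copies`
#' total plasmids.  Default parameters are representative values placing
#' the circuit in the oscillatory regime; output is the cI protein.
#'
#' @param H Promoter cooperativity (Hill coefficient).
#' @param sponge Include the TetR-sequestering sponge plasmid?
#' @param K0,K1 Hill production parameters.
#' @param gamma Protein decay rate (per generation).
#' @param sponge_copies,k_bind,k_unbind Sponge pool size and binding rates.
#' @export
repressilator <- function(H = 2, sponge = FALSE, K0 = 250, K1 = 10,
                          gamma = 1, sponge_copies = 5, k_bind = 10,
                          k_unbind = 1) {
  f <- function(x) K0 / (K1 + x^H) - gamma * x
  xbar <- round(stats::uniroot(f, c(0, K0 / gamma + 1))$root)
  if (!sponge) {
    reaction_network(
      species = c("TetR", "cI", "LacI"),
      reactions = list(
        reaction(c(0, 0, 0), c(1, 0, 0), hill_repression(K0, K1, H, 3),
                 name = "TetR_production"),
        reaction(c(0, 0, 0), c(0, 1, 0), hill_repression(K0, K1, H, 1),
                 name = "cI_production"),
        reaction(c(0, 0, 0), c(0, 0, 1), hill_repression(K0, K1, H, 2),
                 name = "LacI_production"),
        reaction(c(1, 0, 0), c(0, 0, 0), mass_action(gamma), name = "TetR_decay"),
        reaction(c(0, 1, 0), c(0, 0, 0), mass_action(gamma), name = "cI_decay"),
        reaction(c(0, 0, 1), c(0, 0, 0), mass_action(gamma), name = "LacI_decay")),
      output = "cI",
      state0 = c(xbar, xbar, xbar))
  } else {
    # species: TetR, cI, LacI, Sp (free sponge), Cx (TetR:Sp complex)
    reaction_network(
      species = c("TetR", "cI", "LacI", "Sp", "Cx"),
      reactions = list(
        reaction(rep(0, 5), c(1, 0, 0, 0, 0), hill_repression(K0, K1, H, 3),
                 name = "TetR_production"),
        reaction(rep(0, 5), c(0, 1, 0, 0, 0), hill_repression(K0, K1, H, 1),
                 name = "cI_production"),
        reaction(rep(0, 5), c(0, 0, 1, 0, 0), hill_repression(K0, K1, H, 2),
                 name = "LacI_production"),
        reaction(c(1, 0, 0, 0, 0), rep(0, 5), mass_action(gamma),
                 name = "TetR_decay"),
        reaction(c(0, 1, 0, 0, 0), rep(0, 5), mass_action(gamma),
                 name = "cI_decay"),
        reaction(c(0, 0, 1, 0, 0), rep(0, 5), mass_action(gamma),
                 name = "LacI_decay"),
        reaction(c(1, 0, 0, 1, 0), c(0, 0, 0, 0, 1), mass_action(k_bind),
                 name = "sponge_bind"),
        reaction(c(0, 0, 0, 0, 1), c(1, 0, 0, 1, 0), mass_action(k_unbind),
                 name = "sponge_unbind")),
      output = "cI",
      state0 = c(xbar, xbar, xbar, sponge_copies, 0))
  }
}

#' Gene expression under antithetic integral feedback (AIF) control
#'
#' The AIF controller steers the mean protein level to the set-point
#' `mu/theta`: `Z1` is produced at rate `mu`, the protein is sensed by
#' producing `Z2` at rate `theta x_2`, the controller pair annihilates at
#' rate `eta z_1 z_2`, and `Z1` actuates transcription at rate `k z_1`.
#' An optional extra negative feedback from the protein to transcription
#' (Hill form \eqn{4 k_{fb}\hat\mu^2/(\hat\mu + x_2)} or its proportional
#' linearisation \eqn{k_{fb}\max(3\hat\mu - x_2, 0)}, reference point
#' \eqn{\hat\mu = \mu/\theta}) damps the single-cell oscillations the
#' bare controller tends to produce while preserving the set-point.
#'
#' @param mu,theta Controller production and sensing rates (set-point
#'   `mu/theta`).
#' @param eta Annihilation rate constant.
#' @param k Actuation rate constant.
#' @param k_fb Extra feedback gain.
#' @param feedback One of `"none"`, `"hill"`, `"proportional"`.
#' @param k_p,gamma_r,gamma_p Gene expression rates.
#' @export
aif_gene_expression <- function(mu = 10, theta = 0.25, eta = 50, k = 2,
                                k_fb = 0, feedback = c("none", "hill",
                                                       "proportional"),
                                k_p = 0.5, gamma_r = 1, gamma_p = 0.5) {
  feedback <- match.arg(feedback)
  muhat <- mu / theta
  base <- list(
    reaction(c(0, 0, 0, 0), c(0, 0, 1, 0), mass_action(mu), name = "Z1_production"),
    reaction(c(0, 1, 0, 0), c(0, 1, 0, 1), mass_action(theta), name = "sensing"),
    reaction(c(0, 0, 1, 1), c(0, 0, 0, 0), mass_action(eta), name = "annihilation"),
    reaction(c(0, 0, 1, 0), c(1, 0, 1, 0), mass_action(k), name = "actuation"),
    reaction(c(1, 0, 0, 0), c(1, 1, 0, 0), mass_action(k_p), name = "translation"),
    reaction(c(1, 0, 0, 0), c(0, 0, 0, 0), mass_action(gamma_r), name = "mRNA_decay"),
    reaction(c(0, 1, 0, 0), c(0, 0, 0, 0), mass_action(gamma_p), name = "protein_decay"))
  if (feedback == "hill" && k_fb > 0) {
    base[[length(base) + 1L]] <-
      reaction(c(0, 0, 0, 0), c(1, 0, 0, 0), hill_feedback(k_fb, muhat, 2),
               name = "hill_feedback")
  } else if (feedback == "proportional" && k_fb > 0) {
    base[[length(base) + 1L]] <-
      reaction(c(0, 0, 0, 0), c(1, 0, 0, 0),
               proportional_feedback(k_fb, muhat, 2),
               name = "proportional_feedback")
  }
  x1bar <- gamma_p * muhat / k_p
  reaction_network(
    species = c("mRNA", "protein", "Z1", "Z2"),
    reactions = base,
    output = "protein",
    state0 = round(c(x1bar, muhat, gamma_r * x1bar / k, 0)))
}

#' Gene expression inside a dividing cell lineage
#'
#' The cell cycle is an `N`-stage clock advancing at constant rate `alpha`
#' per stage (mean cycle length `N/alpha`, cycle frequency
#' \eqn{2\pi\alpha/N} rad per time unit).  When the clock completes a
#' cycle the mother cell divides; the tracked daughter keeps each molecule
#' of the inner network's species either with probability 1/2
#' (`partition = "binomial"`) or exactly half with randomised rounding
#' (`partition = "strict_binary"`).  The division displacement is
#' state-dependent, so this network uses the generalised jump-kernel
#' generator.
#'
#' @param N Number of cell-cycle stages (`>= 2`).
#' @param alpha Stage advance rate.
#' @param partition Partitioning mechanism at division.
#' @param inner Inner [reaction_network()] (default [gene_expression()]).
#' @export
cell_cycle_host <- function(N = 4, alpha = 1,
                            partition = c("binomial", "strict_binary"),
                            inner = gene_expression()) {
  partition <- match.arg(partition)
  if (N < 2) stop("N must be >= 2")
  d_in <- inner$d
  d <- d_in + N
  pad <- function(v) c(v, rep(0, N))
  reactions <- lapply(inner$reactions, function(r) {
    r$reactants <- pad(r$reactants)
    if (!is.null(r$displacement)) r$displacement <- pad(r$displacement)
    p <- r$propensity
    if (p$type == "affine") r$propensity$coef <- pad(p$coef)
    r
  })
  for (i in seq_len(N - 1L)) {
    reactions[[length(reactions) + 1L]] <-
      reaction(unit(d, d_in + i), unit(d, d_in + i + 1L), mass_action(alpha),
               name = paste0("stage_", i))
  }
  kern_ctor <- if (partition == "binomial") binomial_partition_kernel
               else strict_binary_kernel
  delta <- unit(d, d_in + 1L) - unit(d, d_in + N)
  reactions[[length(reactions) + 1L]] <-
    reaction(unit(d, d_in + N), propensity = mass_action(alpha),
             kernel = kern_ctor(seq_len(d_in), delta = delta),
             name = "division")
  reaction_network(
    species = c(inner$species, paste0("stage", seq_len(N))),
    reactions = reactions,
    output = inner$species[inner$output],
    state0 = c(inner$state0, 1, rep(0, N - 1L)))
}

#' Known denominator factor induced by the cell-cycle clock
#'
#' The cell-cycle clock's generator has the dominant non-zero eigenvalue
#' \eqn{\sigma = -\alpha(1 - e^{2\pi i/N})}; the conjugate pair contributes
#' the monic quadratic \eqn{B(s) = |\sigma|^2 - 2\mathrm{Re}(\sigma)s +
#' s^2} to the output denominator, which can be supplied to [pade_solve()]
#' as a known factor.
#'
#' @param N Number of stages (`>= 2`).
#' @param alpha Stage advance rate.
#' @return Coefficients `c(B0, B1)` of the monic quadratic.
#' @export
known_factor_cell_cycle <- function(N, alpha) {
  if (N < 2) stop("N must be >= 2")
  if (alpha <= 0) stop("alpha must be positive")
  sigma <- -alpha * (1 - exp(2i * pi / N))
  c(Mod(sigma)^2, -2 * Re(sigma))
}

#' Synthetic "experimental" single-cell traces
#'
#' Emulates fluorescence time-lapse data: uniformly sampled output
#' trajectories scaled by an unknown constant of proportionality `scale`.
#' Because the normalised PSD (area under the curve = 1) is invariant to
#' the scale, such traces still identify spectral shape parameters.
#'
#' @param network A [reaction_network()].
#' @param Q Number of traces.
#' @param dt Sampling step.
#' @param scale Proportionality constant (`> 0`).
#' @param Tf,Tc Horizon and burn-in.
#' @param seed Base seed.
#' @return An `"experiment_traces"`: list with `values` (n x Q matrix) and
#'   `dt`.
#' @export
synthetic_experiment_traces <- function(network, Q = 100, dt = 0.5,
                                        scale = 1, Tf = 2000, Tc = 100,
                                        seed = 1) {
  if (scale <= 0) stop("scale must be positive")
  if (Q < 1) stop("Q must be >= 1")
  ens <- ssa_ensemble(network, Q = Q, Tf = Tf, Tc = Tc, seed = seed,
                      sample_dt = dt)
  n <- floor((Tf - Tc) / dt)
  V <- vapply(ens$runs,
              function(r) scale * r$samples[seq_len(n), network$output],
              numeric(n))
  structure(list(values = V, dt = dt), class = "experiment_traces")
}

#' Normalised ensemble PSD of experimental traces
#'
#' Averages the per-trace periodograms and normalises the curve to unit
#' area (trapezoidal rule up to the Nyquist frequency), removing any
#' unknown proportionality constant.
#'
#' @param traces An `"experiment_traces"` object.
#' @return Tibble with `omega` and `npsd`.
#' @export
normalized_psd <- function(traces) {
  stopifnot(inherits(traces, "experiment_traces"))
  Q <- ncol(traces$values)
  pgs <- lapply(seq_len(Q),
                function(q) periodogram(traces$values[, q], dt = traces$dt))
  omega <- pgs[[1]]$omega
  m <- rowMeans(do.call(cbind, lapply(pgs, `[[`, "psd")))
  area <- sum(diff(omega) * (m[-1] + m[-length(m)]) / 2)
  tibble::tibble(omega = omega, npsd = m / area)
}

#' Normalise any PSD curve to unit area on a grid
#'
#' @param x PSD object or function.
#' @param omega Frequency grid.
#' @return Tibble with `omega` and `npsd`.
#' @export
normalized_psd_curve <- function(x, omega) {
  f <- as_psd_function(x)
  v <- pmax(f(omega), 0)
  area <- sum(diff(omega) * (v[-1] + v[-length(v)]) / 2)
  tibble::tibble(omega = omega, npsd = v / area)
}
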