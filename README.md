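# ctmcpsd

Power spectral densities of stochastic reaction networks.

Time-lapse microscopy now delivers long single-cell trajectories of
protein and mRNA copy numbers, and the frequency content of those noisy
trajectories carries mechanistic information — oscillation frequencies,
feedback signatures, cell-cycle resonances — that population snapshots
cannot. Connecting a continuous-time Markov chain (CTMC) model of a
reaction network to the power spectral density (PSD) of one of its
species is, however, awkward with standard tools: the periodogram is an
inconsistent estimator that needs many simulated trajectories and still
suffers aliasing, and diffusion approximations break down at the low copy
numbers typical of synthetic circuits. `ctmcpsd` is for systems and
synthetic biologists who have a stochastic network model and want clean,
parametric PSD estimates from a handful of exact simulations.

## The method

For an ergodic CTMC with generator 𝔸, stationary law π and centred output
f(x) = xₙ − E_π(Xₙ), the resolvent function

    G(s) = E_π( f · R(s) f ),   R(s) = ∫₀^∞ e^{−st} T(t) dt

determines the output PSD through S(ω) = 2 Re G(iω). Because the
autocovariance of reaction networks is typically a short sum of
exponential modes, G is well approximated by a low-order rational
function

    G_p(s) = (κ₀ + κ₁ s + … + κ_{p−1} s^{p−1}) / (β₀ + … + β_{p−1} s^{p−1} + s^p).

The package estimates the power-series coefficients of G at a set of
interpolation points s₁, …, s_L ∈ (0, ∞] — the *Padé derivatives* — from Q
exact SSA trajectories of an *augmented* chain: each finite point gets a
bank of shift registers reset at exponential times (so register m + 1
holds the output an Erlang(m+1, s)-lagged time in the past), while the
point at infinity uses stationary generator moments E_π(f 𝔸^m f) with
variance-reducing covariates. The κ, β coefficients then solve a small
least-squares system, and the approximant is validated against direct
resolvent estimates at held-out points before the PSD is reported.

For linear (affine-propensity) networks the PSD is exact:
S(ω) = −2 eₙᵀ(ω²I + A²)⁻¹AΣeₙ with Σ from the Lyapunov equation, and the
spectrum of a stimulated linear circuit decomposes into an intrinsic term
plus gain-modulated input spectra — which also yields a *composite*
estimator for interconnected networks (e.g. an oscillator driving a gene
expression cascade) without simulating the joint system.

## Worked example

The two-stage gene expression model (transcription rate 10, mRNA decay 1,
translation 2, protein decay 0.5) has the exact protein spectrum
(40ω² + 120)/(ω⁴ + 1.25ω² + 0.25). The semi-analytic pipeline recovers it
from ten simulated trajectories:

```r
library(ctmcpsd)

net <- gene_expression(k_r = 10, gamma_r = 1, k_p = 2, gamma_p = 0.5)
fit <- pade_psd(net, p = 2, s = Inf, rho = 4, s_test = c(0.5, 1, 2),
                Q = 10, Tf = 1e4, Tc = 1e2, seed = 1)
psd_polynomial(fit$rational)
#> <psd_rational> S(w) = P(w^2)/Q(w^2)
#>   P: 120.4460,  40.0473
#>   Q: 0.248522, 1.255941, 1.000000 (ascending, monic)
fit$validation
#> # A tibble: 3 × 7   (all points pass at the 10% threshold)
#>       s G_direct G_pade abs_err rel_err    se pass
#>     0.5    111.   112.   0.606  0.00545 1.36  TRUE
#>     1       71.4   71.6  0.145  0.00202 0.619 TRUE
#>     2       41.1   41.1  0.0412 0.00100 0.308 TRUE
```

The estimated numerator (40.05ω² + 120.4) and denominator
(ω⁴ + 1.256ω² + 0.2485) sit within a percent of the analytic
coefficients; `psd_eval(fit$rational, omega)` evaluates the curve,
`autoplot(fit)` draws it, and `glance(fit)` summarises peak frequency,
stability and validation in one row. The exact reference comes from
`psd_rational_exact(linearize(net))`, and `ensemble_psd(net, ...)` gives
the periodogram baseline with its one-standard-deviation band.

A catalog of example networks is built in: `list_fixtures()` covers
birth-death, telegraph, gene expression, RNA splicing, incoherent
feedforward and negative feedback (with their tabulated analytic
spectra), the repressilator (with an optional TetR-sequestering sponge
plasmid), gene expression under antithetic integral feedback, a
self-regulating gene with Hill repression, and gene expression inside a
dividing cell lineage with binomial or strict-binary molecule
partitioning (a state-dependent jump kernel). A thin command-line front
end lives at `inst/cli/padepsd`.

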