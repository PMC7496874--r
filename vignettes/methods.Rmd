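---
title: "Models and methods: losing metamorphosis through direct development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: losing metamorphosis through direct development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ddevo)
```

`ddevo` couples two machines: a size-structured consumer–resource model
analysed with adaptive dynamics, asking when a metamorphosing life history
is abandoned in favour of direct development; and a Bayesian test of
correlated evolution between direct development (`D`) and large eggs
(`E`) on a phylogeny. This vignette explains the models, their
assumptions, the numerical choices, and what the synthetic data do and do
not emulate.

## The size-structured consumer–resource model

Consumers feed on two semichemostat resources. Resource 1 (the "larval"
food) is available to everyone; resource 2 requires a body mass of at
least `w_min` grams *and* a morphology at least partly specialized on it.
Each resource recovers as `delta * (X_max - X)` and is drained by the
population's realized ingestion, so the supply rate `delta * X_max`
(mg L⁻¹ day⁻¹) is the environmental control variable.

An individual carries irreversible mass `x` (structure) and reversible
mass `y` (fat, gonads); total mass `w = x + y` determines all rates.
Attack rates are hump-shaped in `w`,
`A_max * (w / w_opt * exp(1 - w / w_opt))^alpha`, with the hump height
scaled by the degree of specialization: `(1 - psi)` on resource 1, `psi`
on resource 2. Handling time `xi1 * w^-xi2` is shared by both foods,
intake follows a Holling type-II response with encounter-proportional
diet preference, assimilated intake (`kappa_e`, with `conv` grams per mg
ingested) covers maintenance (`m1 * w^m2`) first, and the remainder grows
the body (a fixed fraction `kappa_x` to structure) or — in adults — is
routed to reproduction (fraction `kappa_rep`). Starvation drains
reversible mass only; an individual dies when `y/x` falls below
`q_starv`.

A note on the diet rule: with a single shared handling time, intake is
linear in the effective encounter rate, so a literally optimal forager
would always specialize on the momentarily richer food. The
encounter-proportional rule (`phi1 = a1 X1 / (a1 X1 + a2 X2)`) is the
standard opportunistic limit, never drops a resource, and is within ~17%
of the corner optimum in the worst case; the tests assert that bounded
suboptimality rather than exact optimality.

Four traits evolve: larval specialization `psi_L`, the extent of
metamorphosis `theta`, mass at metamorphosis `w_J`, and mass at birth
`w_b` (both masses bounded below by 0.0001 g). Larvae express `psi_L`;
at `w = w_J` they metamorphose into juveniles expressing
`min(1, psi_L + theta)`, losing a fraction `meta_loss * theta` of their
reserves and dying with probability `rho * theta`. Maturation occurs at
`w_A`. Fecundity is reproductive energy divided by the offspring cost
`c0 + c1 * w_b` — the size–number trade-off. When `w_b >= w_J`
metamorphosis completes before birth (direct development): there is no
free-living larva, the newborn survival factor `1 - rho * theta` applies
at birth, and the mother pays the metamorphosis surcharge, multiplying
the offspring cost by `1 + meta_loss * theta` so fecundity declines with
`theta`.

### Life-history integration and equilibrium

`integrate_life_history()` integrates a cohort in constant food with a
fixed-step RK4 scheme (step `h = 0.25` d, widened fourfold in the slow
adult phase) that lands exactly on the mass thresholds; survival is
integrated exactly within steps. It returns `R0` (expected lifetime
offspring), the expected lifetime ingestion of each food per newborn, and
survival-weighted stage occupancies, which at equilibrium are the stable
size distribution up to the factor `b`.

`solve_equilibrium()` finds `(X1*, X2*, b*)` with `R0 = 1` (to 1e-10) and
`delta * (X_max_i - X_i*) = b* * Gamma_i`. The fast path is a 2-D damped
Newton iteration started from the ray `X = t * X_max` (where `log R0` is
monotone in `t`); because larval starvation makes `R0` cliff-like at low
food, a fallback exploits monotonicity of `R0` in each density: solve
`R0(x1(X2), X2) = 1` by a 1-D bracket in `X1` and drive the
resource-balance residual to zero in `X2`, bracketing from the viability
boundary where the residual is guaranteed negative. Dynamical (ecological)
stability of the equilibrium is *not* assessed; see the individual-based
model below for why that matters here.

### Adaptive dynamics

Invasion fitness is `log R0` of a mutant in the resident's equilibrium
food environment — sign-equivalent to the invasion exponent at an
equilibrium attractor and far cheaper. Selection gradients are central
differences (relative step 1e-4, one-sided at the trait boxes).
`find_singular()` performs quasi-Newton root finding on the gradient in
internal coordinates that log-transform the two mass traits: the gradient
in `w_J` is extremely stiff because larval growth decelerates toward the
metamorphosis threshold, and log coordinates with small Jacobian steps
(2e-4) keep Newton stable. Traits pinned at a box boundary with an
outward gradient are reported in `pinned`; in addition a trait can be
pinned at a *viability cliff* — e.g. selection pushes `w_J` down to the
point where post-metamorphs could no longer reach `w_min` — which the
solver detects by probing resident viability a step further along the
gradient. Classification combines the mutant Hessian (local
invadability) with the Jacobian of the selection gradient under an
identity mutational covariance (convergence), with an explicit
indeterminate flag when eigenvalues sit within tolerance of zero.

`continue_in_parameter()` tracks a singular strategy in a model parameter
(natural-parameter stepping, adaptive step halving, warm-started
equilibria). Terminal events are bracketed by bisection: a *fold* when
the singular strategy ceases to exist (the CSS meets its repeller), an
*extinction boundary* when the resident equilibrium loses viability. The
canonical equation `d(traits)/dt = k * N* * g` is integrated with
adaptive Euler steps capped at 2% trait change, clipping at the boxes;
the prefactor (mutation rate × variance × ½) is folded into one rate
constant, so time is in scaled evolutionary units.

### The packaged parameter presets

The functional forms above follow the Persson-type planktivore models
this family of studies adapts. The `fat_reserves` preset places the
baseline supply rates at 0.0165 mg L⁻¹ day⁻¹ (`delta = 0.25` day⁻¹,
`X_max = 0.066` mg L⁻¹), with `w_min = 0.002` g, `w_A = 0.1` g, moderate
metamorphosis costs (`rho = 0.15`, `meta_loss = 0.3`), uniform background
mortality (0.01 day⁻¹ in every stage, i.e. size-independent), and an
offspring cost `4e-4 + w_b` grams. These choices were fixed once, by
bioenergetic scaling, to produce the empirically motivated regime at high
supplies: larvae completely specialized on resource 1 (`psi_L = 0`
pinned), full metamorphosis (`theta = 1` pinned, post-metamorphic
specialization 1), an interior `w_J` set by the larval/juvenile
growth-rate crossover, and small offspring. Under declining primary
supply the model then reproduces, emergently: shrinking `w_J`, rising
`w_b`, falling age at metamorphosis, a fold of the metamorphic branch
near supply 0.0012 mg L⁻¹ day⁻¹ beyond which the viable attractor is the
direct developer with `w_b` just above `w_min`; at low secondary supply
(0.0066 mg L⁻¹ day⁻¹) the branch instead dies on the extinction boundary
without a fold. One deliberate limitation: the direct developer in this
parameterization feeds through `psi = psi_L` at every stage, so lowering
`psi_L` hurts adults as well and the strategy never loses *local*
evolutionary stability at high primary supply; the re-evolution of
metamorphosis would require a non-local (jump) mutation.

The `generic_invertebrate` preset is the single-mass phenomenological
variant (no reserves; metamorphosis shrinks the body), and
`toy_symmetric` is a deliberately degenerate configuration — two
identical resources available from birth, one effective trait — whose
singular strategy is `psi_L = 1/2` exactly by exchange symmetry, with
analytically known (disruptive, convergence-unstable) curvature; the
solver and classifier are validated against it.

### The individual-based model

`simulate_ibm()` is the finite-population counterpart: deterministic
within-step physiology (Euler, default 0.5 d), stochastic deaths, births
(Poisson on the reproductive energy flux), per-trait Gaussian mutation
truncated to the boxes, and explicit semichemostat resources driven by
realized consumption in a habitat of `volume` litres. Everything is
reproducible from the seed. Two caveats discovered with it are worth
stating. First, at the baseline supplies the *metamorphic* equilibrium is
dynamically unstable: juvenile maturation is cliff-like in the secondary
food, and the population undergoes slow cohort cycles rather than
settling, so IBM time-averages need not match the (saddle) equilibrium.
The direct-development resident, by contrast, tracks its deterministic
equilibrium to well under a percent, and that configuration is what the
consistency checks use. Second, with mutation on, evolution in the IBM is
mutation-limited; transition experiments (`transition_experiment()`)
therefore vary decline rate and volume with modest replicate counts and
report Wilson intervals rather than point claims.

## Correlated evolution of direct development and large eggs

The phylogenetic engine implements the classic two-binary-trait
framework: a 4-state continuous-time Markov chain on
`(D,E) in {00, 01, 10, 11}` in which simultaneous changes of both traits
have rate zero. The *independent* model has 4 free rates, the
*dependent* model 8 (every transition conditional on the other trait's
state), and the *constrained-dependent* model 7, tying the two gains of
`D` together (`q13 = q24`) — the hypothesis that direct development
arises equally easily on small- and large-egg backgrounds.

Likelihoods use Felsenstein pruning over the four joint states; missing
trait values enter as ambiguity over the compatible states, so the
79%/28% coverage pattern of the motivating amphibian data costs no
special handling. Transition probabilities come from the
eigendecomposition of the generator collapsed into a single complex
matrix product over all branch lengths (with a `Matrix::expm` fallback
for defective generators — note that `ape::matexpo` is inaccurate for
non-reversible generators with complex eigenvalues and is not used). The
root prior defaults to uniform over the four states (stationary
available); polytomies need no resolution because pruning is agnostic to
them. Egg sizes are dichotomized downstream of the reader with `E = 1`
iff size ≥ threshold, the threshold defaulting to the sample mean (2.45 mm
in the motivating dataset).

Bayesian machinery: Metropolis–Hastings on the free rates with
log-normal multiplicative proposals (scale adapted during burn-in toward
30% acceptance) under a hierarchical prior, rate ~ Exponential(mean `m`),
`m` ~ Uniform(0, 100). This fixed-dimension prior replaces the
reversible-jump rate-grouping of BayesTraits; the practical consequence,
verified in the recovery experiment, is that a structurally zero rate is
estimated as *small* (posterior 95% quantile an order of magnitude
below the nonzero rates in favourable runs, but above the strict 10%
bound) and never exactly zero — the conditional
ordering of the rates is recovered, the exact zeros of a reversible-jump
analysis are not. Marginal likelihoods use stepping-stone sampling on the
power-posterior ladder `beta_k = (k/K)^(1/0.3)`, assembled from
log-sum-exp-stabilised per-stone importance ratios; the estimator is
validated to 0.1 nats against the closed-form evidence of a conjugate
exponential–gamma toy wired through the same code, and a parameter-free
model returns its log-likelihood exactly. Support is summarized as
`2 * (logZ1 - logZ0)` with the conventional bands (>2 support, >10 very
strong).

## Synthetic data

`simulate_yule_tree()` grows a pure-birth tree forward in time (waiting
times Exponential(`lambda * k`)), optionally rescaled to a target root
age — 350 Myr in the recovery experiments, amphibian-like. Trait data
come from exact Gillespie simulation of the 4-state chain down every
branch, which respects the no-dual-transition structure by construction
(the event log is asserted in tests); missingness defaults to 21% for
`D` and 72% for `E`, matching the motivating coverage. Generating rates
of order 0.005 Myr⁻¹ put the recovery experiments in the realistic
regime. What the synthetic data do *not* emulate: the topology and
branch-length heterogeneity of a real supertree, phylogenetic error, or
any correlation between missingness and the traits — so passing tests
demonstrate correctness of the machinery, not robustness to those
real-data pathologies.

## Problem sizes and numerical settings

Defaults used by the test suite and the acceptance script: continuations
use ~20 points with bisection brackets at 2% relative width; the
direct-development boundary is classified on a 3×3 grid; recovery uses a
500-tip tree with 30–50k MCMC generations; stepping stones use K = 30
(toy) or K = 8–10 (tree data); the IBM consistency run uses a 2×10⁵ L
habitat for ~1,300 individuals over 1,200 days. Tolerances: `R0 = 1` to
1e-10 at equilibria; resident neutrality below 1e-8; pruning vs
enumeration below 1e-10; singular strategies converged when the scaled
gradient falls below 1e-4 (the mass-trait gradients are scaled by the
trait, i.e. derivatives per log-gram).
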