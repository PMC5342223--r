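---
title: "Numerical analysis of chemostat interaction motifs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical analysis of chemostat interaction motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifsim)
```

# The chemostat mass-balance template

Every motif in this package is a continuous-culture (chemostat) model built
from the same mass-balance template. For a biomass $X$ growing on a
substrate $S$ at dilution rate $D$ (d$^{-1}$) with inflow concentration
$S_{in}$:

$$\frac{dS}{dt} = D\,(S_{in} - S) - f(S)\,X, \qquad
  \frac{dX}{dt} = \bigl(Y f(S) - D - k_{dec}\bigr)\,X,$$

where $f(S)$ is the specific substrate-uptake rate (default Monod,
$f = k_m S/(K_S+S)$), $Y \in (0,1]$ the biomass yield, and $k_{dec}$ a
first-order decay rate. A species feeding a product to another contributes
$+\gamma\,(1-Y)\,f\,X$ to the product's balance, where $\gamma$ is a
dimensionless stoichiometric transfer fraction. All concentrations share
one unit system (molar or kg COD m$^{-3}$; the unit choice only matters to
the thermodynamics module).

Setting every biomass to zero and every substrate to its inflow value
annihilates the right-hand side of every motif — the *total washout*
equilibrium, which therefore always exists and is appended exactly (not
solved for) during enumeration.

# The seven motifs

The interaction catalogue (`list_motifs()`) fixes who eats what and who
inhibits whom; the kinetics and parameters are free. Because a mechanistic
encoding of an interaction sometimes needs the mediating metabolite as an
explicit state, two of the "two-species" motifs carry five states and the
competition motif only three:

* **syntrophy** (+/+, 4 states): $X_1$ converts $S_1 \to S_2$; $X_2$
  consumes $S_2$. The benefit to $X_1$ is encoded as noncompetitive product
  inhibition of $f_1$ by $S_2$, $f_1 \cdot 1/(1+S_2/K_{i,1})$ — the partner's
  removal of $S_2$ relieves the producer.
* **food_chain** (0/+, 4 states): the same chain without the feedback
  factor (pure commensalism).
* **food_chain_inhibition** (−/+, 5 states): the chain, plus the consumer's
  waste product $S_3$ ($dS_3/dt = D(S_{3,in}-S_3)+\gamma_1(1-Y_2)f_2X_2$)
  inhibiting $f_1$ noncompetitively.
* **no_common_metabolites** (0/0, 4 states): two fully decoupled
  substrate–biomass pairs; used throughout the tests because its
  equilibria factor into closed-form pair solutions.
* **waste_product_inhibition** (0/−, 5 states): $X_1$'s product $S_3$
  inhibits $f_2$; $X_2$ grows on an independent $S_2$ and returns nothing.
* **substrate_competition** (−/−, 3 states): both species consume the one
  substrate $S_1$.
* **three_species_food_web** (3 species, 6 states): the bundled worked
  example, a three-tier anaerobic food web in COD units. A chlorophenol
  degrader $X_1$ consumes $S_1$ and requires hydrogen ($S_3$) as secondary
  substrate, $f_1 = k_{m,1}\frac{S_1}{K_{S,1}+S_1}\frac{S_3}{K_{S,3c}+S_3}$;
  a phenol degrader $X_2$ consumes the intermediate $S_2$ and produces
  hydrogen while being noncompetitively inhibited by it,
  $I_3 = 1/(1+S_3/K_{i,3})$; a hydrogenotrophic methanogen $X_3$ consumes
  hydrogen in competition with $X_1$ (the $\gamma_2 f_1 X_1$ sink).

Two modelling choices in the three-tier hydrogen balance deserve note.
First, the inhibition factor multiplying the hydrogen *production* term
defaults to the same $I_3$ that throttles $X_2$'s growth and substrate
consumption (`i2 = "i3"`): production is tied to catabolic flux, so
whatever throttles consumption must throttle production, and only this
choice makes the bundled equilibrium table mass-consistent (the
alternative, factor 1, is available as `i2 = "none"`). Second, the
secondary-substrate affinity $K_{S,3c}$ is set to
$10^{-6}$ kg COD m$^{-3}$ in the bundled example configuration — the value
of the source model this parameterisation descends from; it is a required
parameter, not a package default.

# Growth kinetics

Seven forms are available (`growth_kinetics()`): Monod, Haldane (Andrews)
substrate inhibition, Contois, Tessier, Moser, Hill, and Monod scaled by a
thermodynamic factor. All are zero at $S=0$; all but Haldane are
nondecreasing in $S$; Haldane peaks at $S^\* = \sqrt{K_S K_i}$. Kinetic
constants are per-species parameters (`km1`, `KS1`, ...) so mixed-form
communities are expressed directly.

# Fixed-point enumeration

Chemostat equilibria have *washout structure*: at any equilibrium each
biomass is either strictly positive or exactly zero, so the nonnegative
fixed-point set decomposes over the $2^k$ biomass on/off subsets. For each
subset the reduced algebraic system (off-biomasses pinned at zero) is
solved by a damped Newton iteration with backtracking line search, a
Levenberg–Marquardt step as fallback at near-singular Jacobians, and —
crucially — the active biomasses parameterised in log space. The log
parameterisation means a subset's iteration can only converge to roots
with *its* biomasses strictly positive: boundary roots belong to smaller
subsets and are never rediscovered, which makes the decomposition exact
rather than heuristic.

Starts come from three sources:

1. **Succession warm starts.** Every root already found for a biomass
   sub-subset is inoculated with a small amount ($10^{-5}$ and $10^{-2}$
   times the inflow scale) of each newly active biomass; Newton runs both
   from the raw inoculation state and from its endpoint after a 250-day
   relaxation of the subset-reduced dynamics. This finds the stable
   "invaded" equilibria deterministically.
2. **Random multistart.** `n_starts` points per subset, log-uniform over
   $[10^{-8}, 10\max S_{in}]$ per unknown, with the RNG stream chained by
   subset so that increasing `n_starts` only appends starts (discovery is
   monotone). The default of 200 was set by measuring Newton basin sizes on
   the bundled three-tier example: its interior invasion-threshold saddle
   is reached from only $\approx 2\%$ of random starts, so 200 starts bound
   the per-enumeration miss probability near $10^{-2}$.
3. **Continuation starts** (parameter sweeps only): the roots of the
   neighbouring grid cell, which follow equilibria smoothly across the
   plane and make region maps robust to individual multistart misses.

Converged roots are kept if componentwise $\ge -10^{-10}$ (tiny negatives
snapped to zero), deduplicated at $10^{-6}$ relative tolerance, and sorted
by survivor cardinality then lexicographically by state. Residual norms are
required to be below $10^{-8}\max(1, \lVert x^\*\rVert)$; the test suite
re-verifies them against independently hand-coded right-hand sides. Steady
states (SS ids) are defined by the set of strictly positive biomasses
(threshold $10^{-6}\max S_{in}$), so two distinct fixed points with the
same survivor pattern share an SS id. No global certificate is claimed:
enumeration is systematic multistart, not interval or homotopy continuation.

# Stability classification

`jacobian_at()` evaluates the analytic Jacobian — each motif's equations
are kept symbolically and differentiated entrywise (`stats::D`), validated
against central finite differences to $10^{-6}$ relative — and offers two
spectrum estimators:

* **direct** (default): dense eigendecomposition, backward stable.
* **charpoly**: roots of the characteristic polynomial (Faddeev–LeVerrier
  coefficients, then `polyroot`). This is the classical single-point
  analysis route, and it is kept both for methodological fidelity and as a
  cautionary instrument: polynomial coefficients are an ill-conditioned
  representation of a spectrum. On stiff chemostat fixed points whose
  eigenvalues span four or more orders of magnitude (the three-tier
  example's interior points span $-2.6\times10^4$ to $-0.1$) the small
  eigenvalues are destroyed — their sign can flip, turning a stable node
  into an apparent unstable focus. At degenerate points with repeated real
  eigenvalues (total washout: $\{-D^{(3)}, -(D+k_{dec})^{(3)}\}$,
  a diagonal Jacobian) root extraction splits each multiple root into a
  tight complex cluster with $|\mathrm{Im}| \sim 10^{-5}$, which a
  classifier reads as a *stable spiral* although the exact spectrum is
  real. Analyses that report a spiral at a washout state obtained through
  the polynomial route are reporting this artefact; the package defaults
  to the direct spectrum and labels the washout a stable node.

The eigenvalue classifier maps the spectrum to the standard taxonomy
(node/spiral/saddle/center), folding the saddle-focus into "saddle", with
`zero_tol = 1e-9` deciding when a real (or imaginary) part counts as zero;
any near-zero real part alongside others yields "marginal" rather than a
type. `routh_hurwitz_stable()` decides left-half-plane root location from
the Hurwitz determinant sequence without extracting roots, and is checked
against direct eigendecomposition on 1000 random systems in the tests.

The perturbation (simulation) route displaces a fixed point by
$q = 10^{-3}\max(1,\lVert x^\*\rVert)$ along a random nonnegative-orthant
direction (seeded), integrates 200 days, and declares stability when the
endpoint has returned within $\epsilon = 10^{-4}$. These defaults are
package choices; $q$ must stay small enough not to escape the attractor's
basin in multistable systems, which is why the basin analysis exists as a
separate tool.

# Time integration

`integrate_motif()` wraps a backward-differentiation stiff integrator
(`deSolve`, default tolerances $10^{-6}$ absolute / $10^{-3}$ relative,
matching the common defaults of variable-order stiff solvers), passing the
analytic Jacobian when available. The state handed to the kinetic terms is
clipped at zero inside the derivative callback so that tolerance-level
excursions below zero cannot destabilise the rational kinetics; reported
states are the solver's own, and trajectories started in the nonnegative
orthant stay above $-10\,\mathrm{atol}$. Exact integrator step sequences
are platform details; all downstream analyses are tolerance-bounded, never
bitwise.

`settling_time()` operationalises "time to steady state" as the earliest
time after which *every* component stays within a relative band (default
1%, absolute floor `atol`) of its final value. The band matters: on the
bundled three-tier example from all-0.1 initial conditions the 1% band is
entered for good at $\approx 52$ days, while visual flatness of the
trajectory plot (agreement to three significant figures) corresponds to a
band of roughly 0.1–0.3% and $\approx 70$ days. The default stays at 1%;
report the band alongside any settling time.

# Parameter-plane sweeps and basins of attraction

`operating_diagram()` enumerates and classifies fixed points at every node
of a two-parameter grid and labels each cell by its combination of
(steady state × stability multiset); identical combinations share a region
id numbered by first appearance in row-major order. For the bundled
three-tier example, an 11×11 grid over
$D \in [0.05, 0.6]$, $S_{1,in} \in [0.5, 10]$ — ranges chosen to span the
washout transitions, since at this parameterisation total washout of the
community requires $D \gtrsim 0.5\,$d$^{-1}$ — partitions into exactly three
regions: washout only; washout plus a stable/unstable pair of two-species
states; and additionally the stable three-species state (with the
two-species pair then both unstable). Region areas depend on grid
resolution; the legend structure does not.

`basin_of_attraction()` integrates every cell of a grid over two initial
conditions to a long horizon (default 1000 days — dynamics near saddles are
slow) and labels it with the nearest enumerated fixed point, provided the
endpoint lies within $\epsilon = 10^{-3}\max(1,\lVert x^\*\rVert)$;
otherwise "none". `basin_boundary_ratio()` quantifies a two-attractor
boundary by bisection along the ray $X_i(0)/X_j(0) = r$ at fixed Euclidean
norm of the swept pair. In the three-tier example at $D = 0.01$ (the system
is bistable between washout and coexistence there, as it is at $D=0.1$),
with the other four initial conditions at 0.1 and norm 0.1, the boundary
ratio is $\approx 0.69$; the boundary is close to, but not exactly, a
straight ray through the origin — across the $(0, 0.1]^2$ square the local
boundary ratio drifts by roughly $\pm 0.02$, so the single number should be
read at that accuracy.

# Thermodynamic inhibition

The thermodynamics module couples growth to catabolic free energy.
Standard Gibbs energies at the operating temperature come from an order-2
least-squares polynomial through a compound's tabulated reference values
($\ge 3$ temperatures; with exactly three the quadratic interpolates;
extrapolation allowed 25 K beyond the reference range). The reaction energy
is $\Delta G_{rxn} = \Delta G^{0\prime} + RT\ln Q$ with
$Q = \prod S_\pi^{\gamma} / \prod S_\nu^{\nu}$; under COD units, activities
of aqueous compounds are converted to molarity through their molar mass
before entering $Q$ (gases and solids enter unchanged). The inhibition
factor is

$$I_{th} = 1 - e^{\Delta G_{rxn}/RT},$$

zero at equilibrium and approaching one under strongly exergonic
conditions. For endergonic conditions the raw expression is negative,
which would mean thermodynamically driven biomass decay; the package clamps
at zero by default (no catabolic flux when the reaction is infeasible),
with `clamp = FALSE` restoring the raw formula.

`extend_motif()` grafts a reaction onto a motif: one new state per
unmodelled reactant ($dS/dt = -DS - f_{new} X_n I_{th}$) and product
($dS/dt = -DS + \gamma_{new}(1-Y_n) f_n X_n I_{th}$ — a product with zero
inflow still leaves with the outflow, hence the $-DS$ term), the target
biomass equation rebuilt with $Y_{new} f_{new} I_{th}$ where
$f_{new} = f_n \mu_{new}$, and $I_{th}$ re-evaluated from the current state
at every step (activities floored at $10^{-12}$ inside the logarithm).
With no reaction attached the extension is exactly neutral, which the test
suite asserts through full fixed-point and stability comparison. The
clamped exponential is not differentiable everywhere, so extended motifs
fall back to finite-difference Jacobians (recorded in `jac_method`).

The bundled compound table (H$_2$, CO$_2$, CH$_4$, acetate, H$_2$O at four
temperatures) is synthetic reference data: derived from standard-state
formation energies and enthalpies at 298.15 K via the Gibbs–Helmholtz
relation, bundled for examples and tests. Production work should supply a
curated table via `read_compound_table()`. Anabolic/maintenance energy
partitioning, activity-coefficient corrections, and pH speciation are out
of scope.

# The worked example, and what the tests do and do not show

The bundled configuration (`inst/extdata/three_tier_example.yaml`) fixes
the three-tier community at $D = 0.1$ d$^{-1}$, $S_{1,in} = 5$
kg COD m$^{-3}$: four nonnegative equilibria (total washout; two partial
states with the methanogen washed out; three-species coexistence), with
washout and coexistence both stable — a bistable operating point. From
all-0.1 initial conditions the trajectory reaches the coexistence state.
The basin example runs at $D = 0.01$, also bistable, where the
initial-biomass ratio $X_1(0)/X_3(0) \approx 0.69$ separates the two
outcomes. Test problem sizes — 11×11 sweep grids, 200 multistarts,
1000–2000-day basin horizons, 0.05-day output resolution over 100 days —
are the package's reference configuration for this example.

These are synthetic chemostat conditions: perfectly mixed, constant
inflow, fixed stoichiometry, no pH or temperature feedback, no lag or
maintenance terms. Passing tests demonstrate that the numerics (algebra,
enumeration, classification, integration) are correct for such models —
not that any particular parameterisation describes a real bioreactor.

# Known limitations

* Fixed-point enumeration is systematic multistart, not certified: a root
  with a pathologically small Newton basin could in principle be missed
  (mitigated by succession warm starts, continuation across sweeps, and
  the measured-default multistart count).
* The characteristic-polynomial stability route is untrustworthy for
  eigenvalue spreads beyond $\sim 10^3$ and is provided for comparison,
  not production use.
* No bifurcation-curve continuation: operating diagrams are grids, and
  region boundaries are resolved only to the grid step.
* Basin maps classify by trajectory endpoint at a finite horizon; orbits
  that have not converged by then are labelled "none" rather than resolved.
* Contois kinetics make growth depend on biomass, which couples the
  washout-subset decomposition only through the substrate balances; the
  enumeration handles this, but closed-form cross-checks in the tests use
  Monod.
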