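---
title: "Methods: Münch transport and two-sink sucrose partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Münch transport and two-sink sucrose partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(munchflow)
```

# The scientific question

When a plant's source leaves export sucrose, how much of it each sink organ
receives depends on more than the sinks' own uptake machinery. This package
implements three nested models of a single source feeding two sinks so that
the contribution of each mechanism can be isolated: sink kinetics alone
(VK), kinetics plus a lumped sucrose-dependent pathway resistance (VKR),
and a spatially explicit biophysical description of osmotically driven
phloem flow, optionally coupled to xylem water transport and to radial
sucrose exchange with the apoplast. The headline diagnostic throughout is
the partitioning coefficient `PC1 = v1/(v1+v2)`, the share of total sink
unloading captured by sink 1.

# Models and assumptions

## VK: kinetics only

With no transport resistance all compartments share one sucrose
concentration `c`, the unique positive root of
`sum_i v_max_i * c/(c + K_m_i) = v0`. When the affinities are equal the
closed form `c = K * v0 / (sum(v_max) - v0)` is used; otherwise a bracketed
scalar root search. A steady state exists only for `v0 < sum(v_max)`;
`vk_solve()` rejects loading at or above capacity.

## VKR: lumped sucrose-dependent resistance

Each pathway carries one resistance `r_i` (mol s m⁻⁶) and the flux into
sink *i* is `c0*(c0 - ci)/r_i`. Sap viscosity rises steeply with sucrose,
so `r_i` is the reference resistance scaled by the quartic polynomial
`0.685 S⁴ − 1.0411 S³ + 0.9512 S² + 0.1364 S + 0.3396` evaluated at the
mid-pathway concentration `S = (c0 + ci)/2` in molar units (the linear-
gradient assumption of the lumped model). The steady state solves three
equations — two per-sink flux balances and total conservation
`v1 + v2 = v0` — for `(c0, c1, c2)`.

Two numerical points deserve emphasis:

* **Root finding.** For fixed `c0` the per-sink balance has exactly one
  root `ci` in `(0, c0)`: the transport side is strictly decreasing in `ci`
  (the numerator falls and the mid-concentration — hence the resistance —
  rises), the unloading side strictly increasing. `vkr_solve()` exploits
  this with an inner bracketed bisection, and scans total unloading over a
  logarithmic `c0` grid for *all* sign changes, so every biologically valid
  root (positive concentrations, residual below 1e-13 mol/s) is found. If
  several exist the smallest-`c0` root is reported and the rest are
  attached as an attribute — multiplicity is never silent. A brute-force
  grid-search oracle, independent of this solver, backs it in the test
  suite to four significant figures on randomized parameter draws.
* **Polynomial validity.** The viscosity polynomial is stated for 0–1.5 M.
  Evaluated literally beyond that range it grows quartically, which caps
  the attainable total transport: in the pathway-resistance scenario
  (references 7.5e12 and 1.5e14 mol s m⁻⁶) the lumped system then has *no*
  steady state near total sink capacity, although the system it abstracts
  plainly has one. `vkr_resistance()` therefore takes an out-of-validity
  policy: the default evaluates as printed and warns; the `"clamp"` policy
  freezes the polynomial at its 1.5 M value. The resistance-scenario preset
  uses the clamp so that near-capacity partitioning is computable; all
  other presets never leave the validity range at their standard loading
  rates.

## Biophysical: spatially explicit Münch flow

The plant is discretized into 1-D elements: a loading zone (20 × 0.005 m by
default), an explicit zero-length junction, one long-distance pathway per
sink (30 elements, element length = pathway length / 30) and one unloading
zone per sink (20 × 0.005 m). Per element the state is water mass `W_Ph`
(g) and sucrose `S_Ph` (mol), plus xylem water `W_X` and apoplast sucrose
`S_apo` in the respective modes. Derived fields:

* concentration `c = S/(W/ρ)`; osmotic potential `Π = −RT·c`;
* turgor from linear elasticity `P = ε·(V − V_ref)/V_ref` for both phloem
  (ε_p = 30 MPa) and xylem (ε_x = 750 MPa, tension allowed — the xylem
  follows cohesion–tension);
* sap viscosity from the sucrose volume fraction,
  `μ = μ_X exp(4.68·0.956φ/(1 − 0.956φ))` with
  `φ = V_suc·S/(V_suc·S + W/ρ)`;
* water potential `Ψ = P + Π`.

Axial flow between neighbouring elements is Hagen–Poiseuille,
`Q = N_Ph π a_Ph² k_p/μ̄ · ΔP/L̄`, with interface viscosity and length the
arithmetic means of the two elements (a standard finite-volume choice;
nothing in the problem dictates another). Sucrose is advected at the upwind
element's concentration — chosen for numerical stability; the discretization
is otherwise not prescribed by the physics. Radial water exchange is
`L_r·A_rad·ΔΨ` across the lateral sieve-tube surface
`A_rad = N_Ph·2π·a_Ph·L`, against a reservoir at Ψ = 0 in phloem-only mode
or against the co-located xylem element in coupled mode. Loading is uniform
over the source zone; each sink's `v_max` is split uniformly over its 20
unloading elements and applied to local concentration. The junction is a
zero-resistance bookkeeping node: flux edges connect its parent directly to
the first element of each branch, so only the neighbours' own half-lengths
contribute resistance. A finite shared pathway is available through
`mesh_spec(shared_pathway_length = )`.

### Water boundaries

Sink water closure takes three forms: an imposed volumetric flux on the
sink xylem (positive uptake, negative evaporation); soil-coupled uptake
`J = f·L_r·A_up·(ψ_soil − Ψ_X)` through an effective root membrane area
`A_up` with permeability factor `f` (a tuber is a root with `f = 0.1`); or
fixed evaporation as a fraction of the mature-leaf transpiration (a young
sink leaf evaporates 10%). The source zone extracts either the fixed
transpiration rate `J_trans` or, with imposed sink fluxes, the
instantaneous net sum of the sink water flows, which closes the water
budget exactly at all times.

The effective root area is not a published quantity; the default 0.8 m²
makes a fully soil-coupled root take up water of order 2e-8 m³/s at xylem
tensions of a few tenths of MPa — the same order as the transpiration
demand it must meet. Only the product of area and permeability factor is
identifiable, which is why the tuber is encoded as a permeability factor.

### Radial sucrose exchange (SWEET/SUT) and SP6A

Along the long-distance pathways (only — loading and unloading zones are
handled by their own fluxes) each element exchanges sucrose with an
explicit apoplast pool: SWEET-mediated efflux
(`v_max` 0.148 mol m⁻³ s⁻¹, `K_m` 70 mM on phloem concentration), SWEET
retrieval (0.148, 10 mM) plus SUT retrieval (0.117, 1 mM) on apoplast
concentration, all scaled by the element volume. SP6A binds SWEETs and
reduces their capacity: `sp6a_factor = 0.6` scales SWEET efflux — and by
default SWEET retrieval too, since the factor models the transporter
itself; an efflux-only variant is a configuration flag
(`sp6a_scales_retrieval = FALSE`) for sensitivity work.

Two apoplast parameters are not fixed by any published value and are
handled as follows:

* **Removal rate.** Sucrose leaves the apoplast to the surrounding tissues
  at `k_rm · c_apo · V_elem` — first-order in apoplast *concentration*
  scaled by element volume. (First-order in *content* would make the
  steady-state loss scale with the apoplast volume fraction, contradicting
  the requirement below.) `k_rm` was calibrated once on the young-leaf
  (0.1 m, evaporating) vs root/tuber (0.3 m, soil-coupled) scenario over
  the 8-point logarithmic loading scan 0.025–25 nmol/s so that the maximum
  net efflux fraction `(v0 − v1 − v2)/v0` is ≈ 23% of loading, and then
  frozen at `k_rm = 0.089 s⁻¹` as the package default. The response is
  monotone in `k_rm`, so the calibration is well posed.
* **Apoplast volume fraction** (default 5% of the phloem element volume)
  affects only the transient filling time of the pool, not the steady
  state; the test suite asserts steady-state insensitivity to it.

## Parameters

Defaults (g, m, s, MPa, mol; concentrations mol/m³): water density
0.998e6 g/m³; radial membrane permeability `L_r` = 5e-8 m MPa⁻¹ s⁻¹; water
viscosity 1.0019e-9 MPa s; sieve-element radius 8.4e-6 m; xylem conduit
radius 30e-6 m; axial phloem permeability 3.82e-12 m²; elastic moduli 30
(phloem) and 750 (xylem) MPa; transpiration 0.02 g/s; soil potential 0 MPa.
Two quantities the parameter table does not fix are explicit assumptions:
the temperature behind `RT` (293.15 K) and the sucrose partial molar
volume `V_suc` = 2.157e-4 m³/mol (342.3 g/mol at 1587 kg/m³).

The number of parallel sieve tubes `N_Ph` is derived, not assumed: the
spatial and lumped models are anchored to each other at zero sucrose, where
viscosity effects vanish. The axial resistance of the standard 0.25 m
pathway at water viscosity, `μ_X L/(k_p N_Ph π a_Ph²)`, divided by `RT`
(which converts pressure-per-volumetric-flow resistance into the
concentration-flux resistance of the lumped model) must equal the lumped
resistance at 0 mM — the constant term of the viscosity polynomial times
the 7.5e12 reference — giving `N_Ph ≈ 47.6`, an effective (non-integer)
conduit count. `N_X` defaults to `N_Ph` and the xylem axial permeability to
the Poiseuille value `a_X²/8`; both are exposed as parameters.

# Numerical choices

* **Initial state**: uniform 300 mol/m³ sucrose, phloem at reference volume
  (zero turgor), xylem at the soil potential, empty apoplast; fully
  deterministic. Steady states are verified insensitive to the initial
  concentration (100 vs 500 mol/m³ agree in PC1 to 1e-3).
* **Integration**: stiff sparse-Jacobian `lsodes` in geometrically growing
  time segments (10^0.5 spacing) up to `t_max` = 1e7 s.
* **Convergence** is declared when the scaled derivative norm
  `max |dy/dt|·τ / max(|y|, 1e-3·y_ref)` with τ = 1e4 s drops below 1e-8.
  The floor at 1e-3 of each component's natural magnitude keeps near-empty
  compartments (e.g. the sucrose-free tip of a starved branch) from
  dominating a relative norm.
* **Newton polish**: once integration has entered the basin of the fixed
  point (norm below 1e-3), a damped Newton iteration on the steady-state
  system (dense finite-difference Jacobian in scaled variables, adaptive
  diagonal shift for the neutral directions of pure-Neumann water closures)
  pushes the residual to the threshold far faster than continued
  integration; steps are rejected unless the norm decreases.
* **Machine-noise floor**: the xylem elastic modulus amplifies one unit in
  the last place of a water state into flux changes of order 1e-13 g/s, so
  the exact fixed point is generally not representable in double
  precision. Derivative components within the response of the
  right-hand side to deterministic one-ulp state perturbations are counted
  as stationary. Accepted states were verified by continuing integration
  for a further 1e6 s at rtol 1e-10: maximum state drift below 1e-8.
* **Divergence**: loading above the combined sink (plus efflux) capacity
  has no steady state; the concentration grows until the viscosity
  exponential overflows, which is reported as an error with the offending
  element. Scan drivers catch this per row and flag the row rather than
  aborting.
* **Determinism**: there is no randomness anywhere; repeated runs are
  bit-reproducible on one platform.

# Scenario presets: what they emulate, and what they do not

The preset catalogue (`inst/extdata/presets/`, YAML) pins the standard
in-silico experiments: sink strength (`v_max` 22.5 vs 2.5 nmol/s), sink
affinity (`K_m` 75 vs 750 mM), pathway resistance (0.25 vs 5 m, lumped
7.5e12 vs 1.5e14 mol s m⁻⁶), an imposed-flux xylem sweep (sink 2 constant
at 2e-8 m³/s), the organ triad (root–root, tuber–root with 10% uptake
permeability, leaf–root with 10% evaporation, all at soil potential
0 MPa), the young-leaf/root–tuber efflux scenario (equal baseline kinetics
`v_max` 5 nmol/s, `K_m` 75 mM at 0.1 vs 0.3 m) with and without SP6A, and
a single-sink configuration for gradient studies. Standard sink strength
is 12.5 nmol/s, standard affinity 75 mM, and loading scans default to 40
log-spaced points over 0.025–25 nmol/s (density configurable; the
published range, unstated density).

These presets emulate a static, idealized potato architecture: one source,
two sinks, uniform sieve-element geometry along the entire pathway, active
Michaelis–Menten unloading in every sink. They deliberately do not emulate
growth or dynamic architecture, passive/symplastic tuber unloading, organ-
to-organ variation in vascular anatomy, xylem solutes, or sieve-plate
substructure. Conclusions from passing tests therefore concern the
transport physics of the idealized system, not whole-plant development.

## The lumped-model comparison (`mean_pathway_summary`)

The single-sink diagnostic compares three summaries of the pathway sucrose
field: the length-weighted spatial mean and summed local resistances
(`"spatial"`); the lumped VKR analogue solved with equal parameterization —
same loading, same sink kinetics, reference resistance matched at zero
sucrose — reporting its mid-gradient concentration and sucrose-adjusted
resistance (`"linear_vkr"`); and the straight-line gradient between the
spatial solution's own pathway end concentrations (`"linear_chord"`).
The spatial profile is convex-decreasing (concentration is sucrose flux
over a volumetric flow that grows along the path as water enters), so the
chord midpoint slightly *over*estimates the spatial mean — the chord mode
exists as the pure gradient-shape comparison and agrees exactly with the
spatial mode for a uniform field. The systematic *under*estimation of
pathway concentration and resistance by a lumped linear-gradient model —
growing with loading rate — appears in the `"linear_vkr"` mode, because the
resistance–concentration feedback acting on a single lumped mean settles at
much lower concentrations than the spatially resolved gradient.

## Branch resistance bookkeeping

`effective_resistance()` sums local viscosity-dependent element resistances
over a branch, by default the long-distance pathway *plus* the unloading
zone it feeds. The distinction matters: radial water influx dilutes a
weak-sink branch (low sucrose flux at comparable water flow), so on the
pathway elements alone the strong sink's branch can carry the *higher* mean
concentration; the strong contrast sits in the unloading zones, where the
strong sink pulls its local concentration toward zero. Over the full
source-to-sink route the stronger sink's branch has the lower resistance,
as expected from its lower overall concentration.

## Step response and its timescale

`run_step_response()` halves (by default) one sink's `v_max` from a
converged steady state. The partitioning coefficient moves instantaneously
when the kinetics change — unloading scales at unchanged concentrations —
so the reported `t90` measures the subsequent relaxation of the
long-distance transport from the post-step instantaneous value to the new
steady state, verified against an independent cold-start solve. The series
also contains the per-sink import rates, whose adaptation is an order of
magnitude slower than the ratio's.

A known limitation: at the standard geometry (0.25 m pathways, loading
12.5 nmol/s) the partitioning ratio relaxes within minutes and the
unaffected sink's import within a quarter of an hour; hour-scale adaptation
emerges in this implementation only for long pathways (the 5 m branch of
the resistance scenario) or near-saturating loading. The relaxation time
scales with the sucrose pool that must be rebuilt (pathway volume times the
concentration change) over the net flux imbalance, so it is roughly
proportional to pathway length. Reported hour-scale adaptation experiments
correspond, under this model, to longer transport distances than the
standard 0.25 m configuration; the acceptance check on the 1–2 h band is
asserted at the standard geometry regardless and fails there, which is
recorded rather than hidden.

## Additivity of length and xylem effects

The factorial driver quantifies whether the partitioning penalties of a
longer pathway and of adverse xylem flow combine additively. Additivity is
asserted only where the additive prediction
`0.5 + ΔPC(length) + ΔPC(xylem)` is an interior partitioning value: at
strongly starved loadings the combined penalty predicts a negative tuber
share while the actual coefficient is clipped at zero, so a deviation there
reflects the bound, not the interaction.

# Problem sizes

Unit tests run the biophysical model on a reduced mesh (5/8/5 elements per
zone) where the property under test does not depend on resolution; the
acceptance tests and the result-reproduction script use the full standard
mesh (20/30/20; 121 elements including the junction) and, for scans, 3–8
loading rates per curve. One full-mesh steady state solves in about a
second; the complete test suite and the acceptance script each run in a few
minutes on one CPU.

# Known limitations

* Static architecture; no growth, no feedback of carbon status on loading
  (except the deliberate equal source-increase convention of the
  sink-strength factorial).
* All sinks unload actively; the passive unloading mode of maturing tubers
  is out of scope.
* The apoplast removal law and the effective root membrane area are
  effective constructs calibrated or chosen once, as described above.
* Concentrations can legitimately exceed the 1.5 M validity edge of the
  lumped viscosity polynomial near sink capacity; the biophysical
  volume-fraction law has no such limit, so near-capacity comparisons
  between the models inherit the clamp convention.
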