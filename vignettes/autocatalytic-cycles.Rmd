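---
title: "Autocatalytic metabolic cycles: detection, stability theory, and saturation audits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autocatalytic metabolic cycles: detection, stability theory, and saturation audits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autocat)
```

## The problem

An autocatalytic metabolic cycle is a set of reactions that needs one of its
own intermediate metabolites in order to make more of that metabolite.
Glycolysis is the canonical example: two ATP are invested in the priming
phase to gain four in the payoff phase, so ATP is required to make ATP. The
carbon-fixation cycle turns 5 five-carbon sugars plus 5 CO2 into 6
five-carbon sugars; the glyoxylate shunt turns one malate plus two
acetyl-CoA into two malates; glucose import by the phosphotransferase
system spends one pep per glucose and regains two through lower glycolysis.

Such designs are intrinsically unstable: if the intermediates dip, the
cycle slows and can drain to zero; if they accumulate, flux can run away.
This package implements, in one place, the computational machinery for
studying that tension:

* a **data model** for stoichiometric networks (JSON/TSV/SBML import),
* two complementary **detectors** of autocatalytic cycles,
* the **analytic steady-state and stability theory** of the
  single-intermediate cycle and its extensions (arbitrary gain ratios,
  input fluxes, bisubstrate assimilation, reversible reactions),
* **Jacobian analysis** of multi-reaction cycles,
* **ODE simulation** confirming the analytics, and
* **audit tools** that confront the theory's predictions with
  flux/proteomics-style tables, plus a synthetic table generator.

## Detecting autocatalytic cycles

### The formal criterion

A reaction set `R` with intermediate metabolites `M` is an autocatalytic
cycle when (i) each intermediate is both produced and consumed by the set
and each reaction both consumes and produces intermediates; (ii) positive
integer multipliers `i_1..i_k` exist making the total reaction vector
(the multiplier-weighted sum of stoichiometric columns) non-negative on
every intermediate and strictly positive on at least one; and (iii) the
set is minimal — no proper subset is itself an autocatalytic cycle, which
excludes padding a genuine cycle with a disjoint one.

`verify_autocatalytic()` implements this by enumerating multiplier vectors
in increasing total sum (bounded by `max_multiplier`, default 12, and a
search budget beyond which the answer is explicitly "undecided" rather
than a silent miss). Two interpretation choices deserve note, both made
after the literal conditions proved self-contradictory on the package's
own fixtures:

* The sign condition in (i) is evaluated on **gross** substrate/product
  stoichiometry, not on net coefficients. A lumped reaction such as
  `5 c5 + 5 co2 -> 6 c5` has a purely positive net row for `c5`, yet the
  pool is clearly both consumed and produced; the net-matrix reading would
  reject the flagship carbon-fixation cycle.
* Minimality in (iii) tests whether a proper subset is itself a **full**
  autocatalytic cycle on its own touched intermediates — sign conditions
  included. Testing only the multiplier inequality would reject any cycle
  whose gain leaves through a returning branch product (the backbone alone
  "gains" the branch product, but never consumes it, so it is not itself a
  cycle).

Certificates are reported with the assignment of minimal total sum (ties
broken lexicographically). Minimal certificates are not unique in *what*
they grow: for the glycolysis lump, multipliers (priming 1, payoff 1) grow
triose phosphate while (1, 2) grows ATP. The optional `gain` argument pins
the metabolite of interest:

```{r}
net <- autocat_example("glycolysis_atp")
verify_autocatalytic(net, c("priming", "payoff"),
                     intermediates = c("atp", "tp"), gain = "atp")
```

### The graph search

`find_autocatalytic_cycles()` composes the second detector with the first:
cofactors are stripped (`default_cofactors()` lists the usual currency
metabolites; always user-overridable), the network becomes a bipartite
directed graph (metabolite -> reaction for substrates, reaction ->
metabolite for products, externals excluded), all simple cycles up to
`max_len` reactions are enumerated by a Johnson-style depth-first search,
and each candidate backbone is classified:

1. reject if a cycle reaction consumes two cycle intermediates;
2. accept (`multi_product`) if a cycle reaction produces two;
3. accept (`branch_product_path`) if a cycle reaction emits a product
   outside the cycle that returns to it through reactions that neither
   belong to the cycle nor consume its intermediates.

In step 3 we require the branch product to *re-enter* the cycle (reach at
least one intermediate): once material is back on the cycle, the cycle's
own reactions carry it to every other intermediate. Requiring an
independent return path to *every* intermediate separately would reject
the textbook motif `{S + X1 -> X2; X2 -> X1 + X3; X3 -> X1}`, whose only
return runs through `X1`.

The classifier assumes unit stoichiometry (as stated for the screen's
original formulation); candidates violating it — the 5:6 carbon-fixation
lump, the pep-doubling glycolysis lump — are routed to the formal
verifier, and every reported cycle carries its multiplier certificate when
one is computable.

```{r}
find_autocatalytic_cycles(autocat_example("pts"), cofactors = c("atp", "adp"))[[1]]
```

## Stability theory of the single-intermediate cycle

With one intermediate `X`, an autocatalytic reaction `fa` (returning
`1 + delta` units per unit consumed; `delta = 1` is the didactic 1:2
case), a branch reaction `fb`, both irreversible Michaelis-Menten, the
dynamics are `dX/dt = delta*fa(X) - fb(X)`. Besides the ever-present
empty state, the candidate positive steady state is

```
X* = (Vmax,b*KM,a - delta*Vmax,a*KM,b) / (delta*Vmax,a - Vmax,b)
```

and two independent inequalities organize the entire phase diagram
(`classify_domain()`): the branch plateau must exceed the autocatalytic
plateau (`Vmax,b > delta*Vmax,a`, so that large excursions are pulled
back), while the branch must be the *shallower* reaction at the origin
(`Vmax,b/KM,b < delta*Vmax,a/KM,a`, so that the empty state repels).
Domain I (both satisfied) is the only region with a stable positive state;
II drains to zero; III has an unstable threshold; IV diverges. Two
practically important corollaries, both verified property-style in the
tests:

* a stable positive state **requires `KM,b > KM,a`** — branch enzymes must
  bind their substrate *more weakly* than the competing cycle enzyme, and
  no amount of expression tuning can substitute;
* equivalently, at `X*` the branch elasticity must exceed the
  autocatalytic elasticity.

`sensitivity_signs()` gives the closed-form response of `X*` to each
kinetic parameter (activating the cycle raises it, activating the branch
lowers it). `steady_states_with_input()` covers a constant input flux
`fi`: the empty state disappears, and either a single stable state
(branch plateau above `fi + delta*Vmax,a`), a stable/threshold pair, or
divergence results — input fluxes widen the viable parameter range.

Degenerate equalities (plateaus or origin slopes matching to within
relative 1e-12) are reported as `"degenerate"` rather than forced into a
domain; the analysis is built on strict inequalities.

### Bisubstrate assimilation

The assimilating reaction really consumes two substrates: the external
metabolite `A` and the intermediate `X`. At constant `A` each of the four
standard mechanisms (ping-pong, random-order ternary, ordered with `A`
first, ordered with `X` first) collapses exactly to Michaelis-Menten form
in `X`; `apparent_constants()` returns the apparent `Vmax` and `KM`, and
the agreement with the full rate law is exact (checked to 1e-12).
Pushing the two stability inequalities through the apparent constants
(`bisubstrate_stable_region()`) yields scheme-specific bounds: all three
ternary-complex schemes impose a **lower bound on `A`** below which no
stable positive state exists, the random-order and A-first schemes bound
the branch affinity (`KM,b > KX/max(1, KA/KiA)` and `KM,b > KX`
respectively), while the X-first scheme is the most robust — any `A`
above its bound admits a stable state. `xstar_vs_A()` traces `X*(A)`:
zero exactly at the lower bound, divergence where the apparent plateau
reaches the branch plateau.

### Reversible reactions

If the branch reaction is reversible with product `Y` (consumed
downstream at first-order rate `D`), the system becomes two-dimensional.
`reversible_branch_analysis()` solves the steady-state quadratic and
decides stability from the 2x2 Jacobian's trace/determinant conditions.
Fast removal (`D > Vmax,a/KM,a`) reproduces the irreversible constraints;
slow removal admits stable states all the way from `Vmax,b -> Vmax,a` to
`Vmax,b -> Inf`, where `X* -> Vmax,a/D - KM,a`. The equilibrium constant
is normalized to 1 by measuring `Y` in units of `Keq*X`. For a reversible
*autocatalytic* reaction, `reversible_autocatalytic_min_Vmax()` encodes
the sufficient existence condition: the cycle slope at the origin must
exceed the branch slope, which sufficiently high expression always
achieves.

## Multi-reaction cycles

For a chain `X1 -> ... -> Xn` closed by an assimilating reaction with
factor `1 + delta` (analysis valid for `delta <= 1`, i.e. up to 1:2), the
Jacobian at a steady state is cyclic bidiagonal: diagonal
`-(alpha_i + beta_i)`, subdiagonal `alpha_i`, corner
`(1+delta)*alpha_n`, where `alpha_i` and `beta_i` are the cycle and
branch derivatives (`build_jacobian()`, `linearize_cycle()`). Its
characteristic polynomial gives the product criterion: the state is
stable when `prod(1 + beta_i/alpha_i)` exceeds the autocatalytic factor,
and a single position with `beta_i > alpha_i` suffices. At the product
value equal to the factor the Jacobian has a zero eigenvalue — this is
the exact stability boundary, recovered numerically by the two-reaction
bisection in the acceptance script. Steady state also forces the flux
ordering `fb_i <= fa_n <= fa_i` with `sum(fb_i) = delta*fa_n`
(`flux_ordering_check()`), and through the saturation lemma (`fa >= fb`
plus a steeper branch imply `KM,b > KM,a` and lower branch saturation)
connects the sufficient condition to a measurable signature: **branch
reactions of an operating cycle should be less saturated than the
competing cycle reactions**. More unsaturated branch points additionally
damp perturbations faster (`perturbation_response()`, and the paired
simulations in the test suite).

## Numerics

* ODE integration uses `deSolve::lsoda` with relative tolerance 1e-9 and
  absolute 1e-12; concentrations are clipped at zero (with a warning
  beyond integrator round-off, -1e-12).
* Divergence is declared when a concentration exceeds 1e6 times the
  largest Michaelis constant — both enzymes are then fully saturated and
  the imbalance is constant, so growth never reverses. Convergence is
  declared when the residual rate falls below 1e-10 of the plateau scale;
  anything else within the horizon is "undecided". The default horizon is
  1e3 characteristic times (`KM,a/Vmax,a`); phase-diagram sweeps in the
  tests extend it so that the slowest near-boundary cells settle.
* Steady states of n-reaction cycles are solved by damped Newton iteration
  on the balance equations with the analytic Jacobian
  (`solve_cycle_steady_state()`), with step halving on non-improving
  residuals.
* Stability calls within 1e-10 of a zero leading eigenvalue are reported
  as `"marginal"`, never silently rounded to stable or unstable.
* Multiplier search is integer arithmetic held in doubles (exact far below
  2^53); stoichiometric coefficients are validated to be integer-valued.

## The synthetic table generator

`generate_synthetic_tables()` emulates the *structure* of paired
fluxomics/proteomics compendia for a cycle at steady state across growth
conditions: per condition, every enzyme level is scaled by a lognormal
factor (CV 0.4 between conditions by default), the perturbed cycle's
stable steady state is re-solved (unstable draws are rejected and
redrawn), and observed fluxes/abundances are the steady-state values
times lognormal measurement noise. The default kinetics
(`example_audit_cycle()`) is a three-reaction 1:2 cycle designed around
`X* = (1,1,1)` with branches at two positions, branch affinities weaker
than cycle affinities (KM 4 and 3 against 1) as stability demands, and
`beta_1 > alpha_1`.

A deterministic **capacity-probe condition** (branch enzymes at half
their reference level, so intermediates pile up toward saturation) is
appended by default. This models the role of condition diversity in real
capacity estimation: the maximal flux-per-enzyme ratio across conditions
is only a lower bound on the true capacity, and without at least one
near-saturated condition the audit substantially overestimates
saturations. The generator's ground truth records both the true
saturations and the method-recoverable ones (true divided by the
across-condition maximum), which is exactly what a noiseless audit can
return.

What passing these tests does *not* show about real data: the generator
draws independent lognormal enzyme variation and noise, has no shared
covariance across conditions, no systematic measurement bias, no
reversible fluxes, and its capacity probe guarantees a near-saturated
condition that real compendia may lack for poorly expressed enzymes.
Audits of real tables inherit the lower-bound caveat of the capacity
estimate in full.

At the study scale used in the tests (20 conditions, measurement CV 0.1,
50 seeds), the audit's median absolute saturation error is computed by
the acceptance suite itself, and the branch-under-saturation pattern is
recovered at one or more branch points in every noiseless run when
auditing a non-probe condition.

## The audit tools on real-shaped tables

`max_in_vivo_rate()` (maximal flux/enzyme ratio across conditions,
documented as a lower bound), `capacity_and_saturation()` (capacity =
rate x enzyme; saturation = flux/capacity, capped at 1),
`audit_branch_points()` (verdicts `branch_less_saturated` / `similar` /
`branch_more_saturated` with a configurable +-10% similarity band — the
field's sources give no threshold, so the band is this package's choice),
and `audit_regulation()` against the expected-sign rule table: cycle
intermediates, the assimilated metabolite, and branch products should all
inhibit cycle reactions and activate branch reactions, with
reverse-branch reactions oppositely regulated. These rules follow from
the sensitivity analysis: whatever raises intermediates should throttle
the cycle and open the drain.

## Worked example

```{r}
spec <- simple_cycle_spec(fa = mm_kinetics(Vmax = 1, KM = 1),
                          fb = mm_kinetics(Vmax = 2, KM = 4))
steady_state_simple(spec)
tr <- simulate_simple(spec, X0 = 0.5)
tr$outcome
tail(tr$states[, 1], 1)
```

The analytic state `X* = 2` (domain I, zero unstable) is reproduced by
the integrator from any positive start.

## Scope and limitations

* Stability statements are local (linearization); no global basins beyond
  what the one-dimensional phase line gives.
* The cycle enumerator is bounded (`max_len`, `max_multiplier`, search
  budget) and says so when a bound bites; it is deliberately not a
  comprehensive elementary-flux-mode engine.
* Multi-reaction analysis covers the single-assimilation chain topology
  with at most one branch per intermediate; a position feeding several
  branches would be linearized by summing their derivatives, a choice the
  interface does not currently expose.
* The autocatalytic factor is restricted to (1, 2]; higher gains than 1:2
  are rejected rather than extrapolated, since the product criterion's
  derivation is only valid up to that ratio.
* Flux tables must be pre-resolved to non-negative directional magnitudes;
  thermodynamics, compartments, and flux-balance analysis are out of
  scope.
```
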