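---
title: "Reducing reaction networks by balanced complexes: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing reaction networks by balanced complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnreduce)
```

## The model

A biochemical network is a set of irreversible reactions between *complexes*
— the multisets of species on the left- and right-hand sides. With `Y` the
species × complexes composition matrix and `A` the complexes × reactions
incidence matrix of the directed complex graph (one −1 and one +1 per
column), the stoichiometric matrix factors as `N = Y A`. Steady-state flux
distributions form the polytope `S = {v : Nv = 0, vmin ≤ v ≤ vmax}`,
optionally intersected with extra linear constraints such as a biomass flux
pinned near its optimum.

The quantity at the centre of the package is the net flux around a complex,
`[Av]_i` (incoming minus outgoing). A complex is **balanced in S** when
`[Av]_i = 0` for all `v ∈ S`. Species balances make some of these structural:
if a species occurs in exactly one complex, its steady-state balance forces
that complex's net flux to zero (*trivially balanced*, provided the complex
has both incoming and outgoing reactions); the property can then cascade,
e.g. a species occurring in two complexes of which one is already balanced
forces the other to be balanced as well. Sinks and sources can never be
balanced once blocked reactions are removed. All remaining cases are decided
by two linear programs per complex: minimise and maximise `[Av]_i` over `S`.
A complex is declared balanced when both optima lie within `tol` of zero.

## Why removal preserves steady states

For a balanced complex with a single outgoing reaction, balancing reads
`v_out = Σ_p v_in,p`, so the outgoing flux is redundant: deleting the
`l + 1` incident reactions and inserting `l` reactions from each incoming
neighbour to the outgoing neighbour — each inheriting the flux value of the
incoming reaction it replaces — leaves every `[Av]_j` of the surviving
complexes unchanged. Hence `N̄ v̄ = 0` for the mapped flux vector, and this
holds for *every* point of `S`, not just mass-action-consistent ones. Because
the substitution is a sum of fluxes, the reduced network does not depend on
the order in which such complexes are removed; the package still fixes a
deterministic order (trivially balanced first, then ascending index) so runs
are reproducible.

With more than one outgoing reaction the removal is sound only when the
outgoing fluxes are fully coupled. Under mass-action kinetics
(`v_i = k_i x^{y(i)}`) this holds automatically: all outgoing fluxes share
the monomial `x^y`, so their ratios equal rate-constant ratios. The removal
inserts `m·l` reactions with constants `k_p k_q / Σ_q k_q` and records the
monomial substitution `x^y = Σ_p (k_p / Σ_q k_q) x^{y(p)}`. What is preserved
here is the steady-state *monomial vector* φ(x) (and hence the steady-state
concentrations expressible through it), not arbitrary polytope fluxes — the
package therefore validates arbitrary-kinetics reductions at the flux level
(`check_steady_state_preserved()`) and mass-action reductions at the
concentration level (`check_concentration_preserved()`). Since every inserted
reaction column is a sum of original columns, `im(N̄) ⊆ im(N)` and every
conservation law of the original network survives
(`check_conservation_inclusion()`); the reduced model may gain new laws.

Loop insertions (incoming neighbour equal to the outgoing neighbour) carry a
zero stoichiometric column and are discarded. Under mass action, parallel
duplicate reactions are merged by summing constants, which leaves the φ
dynamics exactly unchanged; under arbitrary kinetics parallels are kept as
distinct edges because merging would destroy the one-to-one flux map.

## Tunable parameters

* `tol` (default `1e-9`, flux units of the model, typically mmol/gDW/h):
  both the blocked-reaction threshold and the balancedness tolerance. The
  two share a default deliberately — a complex can only be certified
  balanced up to the same numerical resolution at which fluxes are
  distinguishable from zero.
* `biomass_fraction` / scenarios: `prepare_scenario()` offers
  `irreversible` (honour the model's flags), `reversible` (treat every
  reaction as reversible before splitting) and `biomass-optimal`, which
  constrains the space to near-optimal growth. The optimality constraint is
  implemented as `v_bio ≥ (1 − 1e-6) · optimum` — an equality with a small
  relative slack, since an exact equality sits on the boundary of solver
  feasibility.
* `protect` / `keep_reactions` in `reduce_network()`: species whose
  complexes must survive, and reactions whose incident complexes must
  survive. The objective reaction is always kept, so growth predictions
  remain comparable; `biomass_species()` returns the precursors to protect
  for the growth-preserving experiments.
* Bound bookkeeping for inserted reactions: an inserted reaction inherits
  the bounds of the incoming reaction it replaces; with a single incoming
  reaction the upper bound is additionally capped by the outgoing
  reaction's. For `l > 1` the outgoing bound cannot be attributed to any one
  replacement and is dropped — the reduced space may therefore admit extra
  steady states, which is consistent with the one-directional preservation
  guarantee (original states map into the reduced space, not conversely).
* Essentiality threshold (default 0.01): a knockout is called essential when
  the optimum drops below 1 % of wild type. "Lethal" is not sharply defined
  by an LP, so the cut-off is configurable.

## Preprocessing conventions

Reversible reactions are split into forward/backward pairs
(`<id>__fwd`/`__bwd`); all lower bounds are then zero and all upper bounds
equal to the maximum finite upper bound of the original model (1000 when
none exists). Splitting happens *before* blocked-reaction analysis; the FBA
optimum used for biomass floors is computed before blocked removal, so
numerically marginal models keep a feasible biomass flux. Blocked-reaction
removal is a single pass — removing zero-flux reactions cannot block or
unblock others — and orphaned complexes and species are dropped.

## Numerical choices

The LP layer wraps two pure-R simplex implementations behind one
`solve_lp()` interface. The primary backend is fast and deterministic; every
claimed optimum is verified against the constraints before acceptance, and
failures fall through to a second backend run under private fixed seeds
(its pivot tie-breaking is randomized; the caller's RNG state is saved and
restored, so `solve_lp()` is a pure function) across a ladder of Big-M
penalties. As a last resort on small constraint-free spaces the optimum is
computed exactly by vertex enumeration — the polytope is bounded and the
objective linear, so the optimum is attained at a vertex. Infeasibility is
only declared when independent attempts agree. Within `reduce_network()`,
balanced complexes are re-identified once per round, but each
non-trivially-balanced candidate is re-certified by its two LPs immediately
before removal (removals can enlarge the steady-state space, so a stale
certificate is never trusted); trivially balanced complexes are structurally
forced and skip the LPs.

Null spaces for conservation-law checks use the SVD with rank tolerance
`max(dim) · eps · σ_max`. Complex identity is exact for integer
stoichiometries and uses 12 significant digits for fractional ones, so
deduplication is deterministic. The ODE oracle integrates
`dx/dt = N K φ(x)` with a stiff-capable solver (`lsodar`) and stops at the
root of `‖NKφ(x)‖∞ − tol`, doubling the horizon as needed.

## What the synthetic generator emulates — and what it does not

`random_mass_action_network()` builds a connected complex graph (random
spanning tree plus extra edges) in which every reaction comes as a
reversible pair and the first complexes contain a species unique to them.
This plants three properties by construction: no reaction is blocked (every
reaction sits on a two-cycle), every planted complex is trivially balanced,
and — because rate constants are chosen in detailed balance at a planted
positive state — the mass-action dynamics relax to an equilibrium, so the
ODE oracle terminates by design rather than by luck. Forward constants are
log-uniform on `[0.1, 10]`, spanning two orders of magnitude without making
the systems stiff; planted concentrations are uniform on `[0.5, 2]`.

Real metabolic networks are *not* detailed balanced, are much sparser and
larger, have irreversible reactions, exchange fluxes far from equilibrium
and fractional biomass stoichiometries. Passing tests on the generator
therefore certify the *algebra* of identification and removal (LP
correctness against vertex enumeration, preservation identities,
rate-constant rescaling) — they do not certify scaling behaviour or solver
robustness on genome-scale inputs, for which the SBML path and the CLI are
the intended route. The worked-example network is the bridge: it is small
but contains every motif the method distinguishes (trivially and
non-trivially balanced complexes, a sink, a multi-outgoing balanced complex,
a discarded loop).

The test suite and the acceptance script run at deliberate desk scale:
random networks of 8–12 reactions (100 of them for the oracle-equivalence
check, where vertex enumeration is exhaustive), 20 planted networks for the
ODE-based concentration checks, and 50 sampled flux vertices per
steady-state preservation check. These sizes keep the whole suite around
half a minute while exercising every code path.

## Degenerate inputs and tie-breaks

Reactions whose two sides are identical are rejected at construction (their
stoichiometric column is zero). The empty complex is a first-class node so
exchange reactions satisfy the incidence contract; it can itself be
balanced and removed, except when it is incident to the objective reaction
(which is always kept). A reduction that empties the model entirely is
legal and terminates cleanly. Removal order within a round is fixed
(trivially balanced first, ascending index); candidates whose complex
disappeared or changed out-degree mid-round are skipped and reconsidered in
the next round. `jaccard()` defines the similarity of two empty sets as 1.

## Known limitations

* The multi-outgoing removal under *arbitrary* kinetics (outgoing reactions
  fully coupled in the cone) is implemented but marked experimental
  (`allow_coupled = TRUE`): the flux map distributes incoming flux by
  coupling ratios, and its bound bookkeeping is heuristic.
* The LP backends are dense, pure-R simplex implementations — adequate for
  desk-scale models and correctness work; genome-scale runs would want a
  compiled LP solver behind the same `solve_lp()` interface.
* `read_sbml()` covers the constraint-based subset of SBML Level 3 (+fbc)
  and a Level 2 bound fallback; kinetic laws are written on export but not
  parsed on import (rate constants travel in a kinetics TSV instead).
* Balanced sets depend on the flux bounds; all statements are relative to
  the flux space actually analysed, and the package reports that space
  alongside its results.
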