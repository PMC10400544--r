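---
title: "Max–min driving forces under redox-cofactor swapping: models, MILPs and design choices"
author: "tcosa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Max–min driving forces under redox-cofactor swapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the numerical
choices behind them, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The scientific question

NADH and NADPH are chemically near-identical electron carriers with almost
the same standard redox potential (−320 mV), yet cells keep the NAD(H) pool
strongly oxidized and the NADP(H) pool strongly reduced. Which reactions use
which pool — the *cofactor specificity* of the network — determines how much
thermodynamic driving force a metabolic flux distribution can muster: an
oxidation benefits from a low `[NADH]/[NAD⁺]` ratio, a reduction from a high
`[NADPH]/[NADP⁺]` ratio, and the consumed cofactors must be recycled by other
reactions of the same pool. Whether a given specificity is "good" is
therefore a network property, not a reaction property. The package makes this
question quantitative: it rewires a constraint-based model so that every
redox reaction can, in principle, use either pool, and compares the maximal
attainable driving forces across specificity scenarios.

## 2. Model reconfiguration

Starting from a stoichiometric model (toy-JSON or SBML L3/FBC) and a table of
standard reaction Gibbs energies `Δ_r G'°` (kJ/mol), `buildTcosaModel()`
applies, in order:

1. **Gibbs-energy defaulting** (`assignDefaultDG`): exchange and growth
   pseudo-reactions are `unconstrained` (excluded from driving-force
   constraints entirely — implemented as a thermodynamic-activity flag rather
   than a large negative energy, which keeps the MILP clean); reactions
   without a value, and *pure transporters* (reactant multiset equal to the
   product multiset up to the compartment suffix), receive a low sentinel of
   −100 kJ/mol, tagged `default_sentinel`. The tag, not the numeric value, is
   authoritative: the sentinel is a configuration knob. Transporters receive
   the sentinel even when a computed value exists, so that pure transport is
   treated as thermodynamically (almost) unlimited; coupled translocators
   such as an ATP synthase do not match the multiset test and keep their
   values.
2. **Median imputation** (`imputeRedoxMedians`): redox reactions without a
   computed value get the median energy of all computed reactions that
   consume the same cofactor species, tagged `median_imputed`. This runs on
   the pre-split reaction set so forward/backward copies are not double
   counted. When a reaction consumes several cofactor species (dual-pool
   reactions such as a transhydrogenase), the mean of the applicable
   per-species medians is used — the source procedure is ambiguous here and
   this is our documented choice.
3. **Reversible splitting** (`splitReversible`): every reversible reaction
   becomes an irreversible `_FWD`/`_REV` pair; Gibbs energies are negated for
   the backward copy *except* sentinel-tagged ones, which keep the sentinel
   in both directions so that neither direction is artificially favored.
4. **Cofactor duplication** (`duplicateRedoxReactions`): every reaction using
   exactly one pool (both its oxidized and reduced species) is renamed
   `<ID>[_FWD|_REV]_ORIGINAL_<POOL>_TCOSA` and duplicated as
   `..._VARIANT_<OTHERPOOL>_TCOSA` with the cofactor species substituted at
   identical coefficients, bounds and Gibbs energy (the couples share a
   standard potential, so `Δ_r G'°` carries over unchanged). Reactions
   touching both pools (transhydrogenase-, NAD-kinase- and biomass-like) are
   recorded as dual-cofactor reactions and never duplicated; the
   growth/objective pseudo-reaction is never duplicated either, even when it
   touches only one pool — it is a pseudo-reaction, and duplicating it would
   change the model's objective semantics. All copies derived from one
   original reaction form a *variant group* `A_k` (up to four members for a
   reversible redox reaction; six with a third pool), of which any solution
   may activate at most one.
5. **Triplication** (`triplicateRedoxReactions`) optionally adds a
   hypothetical third couple. Its standard potential may differ from
   NAD(P)H's by `ΔE` mV; the variant's Gibbs energy shifts by
   `−nF·ΔE` per unit stoichiometry of the *reduced* species
   (`redoxPotentialToDGShift`), so lowering the potential by 155 mV makes
   reductions by the new cofactor ~30 kJ/mol easier and its own reduction
   equally harder. At `ΔE = 0` the three-pool model is a pure relaxation and
   provably cannot change any optimum — a property the tests assert.

**Feasibility repair** (`relaxToFeasibility`): when demanded growth is
stoichiometrically possible but no concentration vector achieves `B ≥ B_min`,
a MILP minimizes the number of reactions whose driving-force constraint must
be dropped. Relaxed reactions are retagged `relaxed` and treated as fully
thermodynamically unconstrained afterwards (whether they should instead keep
a finite sentinel is not specified by the method's sources; full relaxation
is our choice and is flagged as such).

## 3. The MILPs

All optimizations share one builder. Variables: fluxes `r ≥ 0`, logarithmized
concentrations `x` within `[ln c_min, ln c_max]` (fixed-unit species pinned
to `x = 0` rather than removed), binaries `z`, and the driving-force floor(s)
`B` (and `B_sub`). Constraints: steady state over internal metabolites, flux
bounds, `r_i ≤ z_i β_i`, the driving-force rows, group exclusivity, and an
optional user hook for extra linear flux constraints.

Numerical choices worth recording:

* **Per-reaction deactivation constants.** The textbook form
  `B ≤ f_i + M(1−z_i)` with one global `M` "above the maximal feasible
  driving force" is not sound when `B` may be strongly negative or a reaction
  is strongly endergonic: the row must be vacuous at `z_i = 0` for *every*
  attainable `B` and `x`. The builder therefore computes a certified envelope
  per reaction (`f_i` extremes over the concentration box) and uses
  `M_i = B_ub − f_i,min + 1`, with `B` bounded by `[min_i f_i,min − 1,
  max_i f_i,max + 1]`. `computeBigM()` exposes the global upper envelope;
  a post-solve audit warns if any driving force reaches it, and a test
  doubles it and asserts the optimum is unchanged.
* **Active sets.** A solver may set `z_i = 1` at `r_i = 0`; reported active
  sets therefore require `r_i >` an `ε` of 10⁻⁶ mmol gDW⁻¹ h⁻¹.
* **Demanded optima.** Fixing `B` at a previously computed optimum (ratio
  analysis, census, minimal swaps) is implemented as `B ≥ optimum − band`
  with a 10⁻³ kJ/mol band, avoiding MILP equality brittleness. The same band
  is the package-wide equality tolerance for "reaches the flexible optimum".
* **Infeasibility semantics.** `B` is a free variable, so a stoichiometrically
  feasible instance is always MILP-feasible; `infeasible` status therefore
  means no flux distribution satisfies the demands at all, cleanly separated
  from a feasible solution with `B < 0` (whose magnitude measures the
  distance from thermodynamic feasibility).
* **Solver.** The shipped backend is HiGHS via the python scipy interface
  (`scipy.optimize.milp`), called in batches through a JSON bridge so that a
  sweep or the exhaustive oracle pays the interpreter start-up once. The
  requested MIP gap is 0; feasibility/integrality tolerances are requested at
  10⁻⁹. The builder/backend split keeps other backends pluggable
  (`MilpConfig@solver`).

**SubMDF.** With subset `S` (by default all cofactor-variant reactions plus
thermo-active dual-cofactor reactions), the model adds `B ≥ B_min`
(0.1 kJ/mol) and `B_sub ≤ f_j + M_j(1−z_j)` for `j ∈ S`, maximizing `B_sub`.
Since the subset constraint set is a subset of the MDF's, `B_sub` dominates
the plain MDF wherever both are feasible — asserted as a property test.

## 4. Scenarios, sweeps, swaps, ratios

* **Scenarios.** Wild type blocks every swapped variant; *single pool*
  additionally reroutes the growth reaction's NADP(H) coefficients one-to-one
  onto NAD(H) and blocks the remaining dual-cofactor reactions (with one pool
  they would couple the pool to itself — our documented choice); *flexible*
  blocks nothing and lets group exclusivity arbitrate; *random* draws
  specificities by fair coin (free pool size) or uniformly conditioned on the
  wild-type pool counts (fixed pool size), deterministically from a recorded
  seed, with infeasible draws reported rather than resampled.
* **Growth grid.** Set points start at 99% of the FBA maximum (the 1% backoff
  avoids numerical brittleness at the LP optimum), descend in 0.05 h⁻¹ steps
  and end at the 0.05 h⁻¹ floor; one grid derived from the wild-type maximum
  is shared across scenarios, set points above a scenario's own maximum being
  reported infeasible.
* **Single swaps** flip one reaction's specificity at a time and re-solve;
  swaps that make the demanded growth stoichiometrically infeasible are
  flagged and excluded. **Minimal swaps** open all complementary variants
  behind binary swap indicators (`r_i ≤ z_swap,i β_i`) and minimize their
  sum subject to reaching the flexible optimum; a count of zero is exactly
  the certificate that the wild type attains the optimum. The indicator is
  per model copy, but group exclusivity ensures at most one copy per enzyme
  carries flux, so the count is per swapped enzyme.
* **Census.** At the fixed optimum, each redox reaction's flux is maximized;
  reactions achieving `r > ε` can participate in *some* optimal solution,
  which accounts for the multiplicity of MILP optima.
* **Ratio analysis.** `ρ = x_NADH + x_NADP⁺ − x_NADPH − x_NAD⁺` is maximized
  and minimized in two independent MILPs at the fixed optimum; only the
  driving-force level is fixed, not the flux distribution (the constraint
  set suggests no more, and this is the less restrictive reading). The pool
  pair is configurable, which also yields the anti-symmetry property used in
  testing.

## 5. The toy generator and what passing tests mean

`generateToy()` builds linear pathways with optional redox-coupled steps,
lumped regeneration reactions (respiration-like NADH oxidation, pentose-
phosphate-like NADPH regeneration) and either a plain product sink or a
biomass-like sink consuming both pools. The packaged fixture
(`toyRedoxFixtureSpec()`) couples a catabolic NAD⁺-reducing step (−20
kJ/mol) to an endergonic NADPH-consuming anabolic step (+15 kJ/mol) with
biomass demands of 0.05 on both pools — the minimal constellation in which
the two-pool architecture, the wild-type-optimality pattern and the
oxidized-NAD(H)/reduced-NADP(H) ratio trend all emerge. Concentration bounds
(10⁻⁶–0.02 M), temperature (298.15 K), `B_min` (0.1 kJ/mol), the growth-grid
step and floor (0.05 h⁻¹) and the 99% backoff are the standard study
conditions and are the generator's defaults. Randomized suites draw 2–4
steps, up to two redox couplings on distinct pools, at most one reversible
non-redox step, and step energies uniform in [−30, 5] kJ/mol — sizes chosen
so the exhaustive oracle stays tractable (≤ 12 reactions after expansion).

The **oracle** (`bruteForceMdf`) enumerates all admissible active sets,
checks stoichiometric achievability by LP, and maximizes the driving-force
floor over each set's concentration polytope — a different algorithm sharing
no code with the MILP builder. Twenty seeded instances agree with the MILP
to 10⁻⁴ kJ/mol in the acceptance suite (observed agreement is at rounding
level).

What passing these tests does *not* show: toy networks have a handful of
reactions, one substrate, no compartments, no membrane-potential-corrected
transport energies, and exact Gibbs energies. Genome-scale behavior —
degenerate alternate optima at scale, sensitivity to eQuilibrator-derived
energy uncertainty, and the published *E. coli* numbers — requires the
external model and energy table; the package's SBML reader, reconfiguration
pipeline, FBA and relaxation machinery are the same code paths, but their
genome-scale outputs are not certified by the desk-scale suite.

## 6. Known limitations

* One MILP backend is shipped; backend independence is designed for but not
  cross-tested against a second solver.
* The exhaustive oracle is exponential in reaction count and guarded at ~12
  reactions; it is a validation tool, not an analysis tool.
* Multi-compartment pH/potential corrections of Gibbs energies are out of
  scope: energies arrive pre-corrected, and the eQuilibrator settings under
  which they were computed are carried as provenance metadata only.
* Enzyme-cost or kinetic considerations are not modeled; driving force is
  the sole thermodynamic currency.
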