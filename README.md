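# tcosa — thermodynamics-based cofactor swapping analysis

`tcosa` is an R package for asking a network-level question about redox
metabolism: **which NAD(H) / NADP(H) specificities of a metabolic network's
oxidoreductases maximize the thermodynamic driving forces available to the
cell, and how far is a given (wild-type) specificity from that optimum?**

It does so by reconfiguring a constraint-based metabolic model so that every
redox reaction exists in one copy per cofactor pool, and then computing
**max–min driving forces** under different specificity scenarios with
mixed-integer linear programming.

## The quantities at the core

For a network with stoichiometric matrix `N` (internal metabolites) and flux
vector `r`, a steady state requires `N r = 0` with `α ≤ r ≤ β`. The driving
force of reaction *i* at logarithmized metabolite concentrations `x` is

```
f_i = −Δ_r G'°_i − RT · (Ŝ_·,i)ᵀ x
```

with `Ŝ` the extended stoichiometry including external metabolites, `R` the
gas constant and `T = 298.15 K`; concentrations are bounded (by default
`10⁻⁶–0.02 M`, protons/water pinned at 1 M). The **MDF** is the largest `B`
such that a steady-state flux distribution exists in which every *active*
thermodynamically constrained reaction satisfies `f_i ≥ B`; activity is
tracked by binaries `z_i` with `r_i ≤ z_i β_i` and `B ≤ f_i + M(1 − z_i)`.
The **SubMDF** relaxes this: only a chosen subset (the redox reactions) must
reach `B_sub`, while the rest only needs `f_i ≥ B_min = 0.1 kJ/mol`. Each
redox reaction's forward/backward and NAD/NADP(/hypothetical third cofactor)
copies form a *variant group* of which at most one may be active
(`Σ_{i∈A_k} z_i ≤ 1`).

On top of these two MILPs the package implements: reversible-reaction
splitting; cofactor duplication/triplication with the paper-style
`_ORIGINAL_/_VARIANT_<POOL>_TCOSA` naming; standard-Gibbs-energy defaulting
(−100 kJ/mol sentinel for unknowns and pure transporters; exchange/growth
reactions unconstrained) and per-cofactor-species median imputation;
minimal-relaxation feasibility repair; wild-type / single-pool / flexible /
random specificity scenarios over a growth-rate grid; single-swap scans; a
minimal-cofactor-swap MILP; variability analysis of the
`[NADH]/[NAD⁺] : [NADPH]/[NADP⁺]` ratio quotient at fixed optimum; and a
deterministic toy-network generator with an exhaustive active-set oracle that
independently certifies every MILP result on small instances.

The MILP backend is HiGHS, reached through a batched bridge to the `python`
interpreter's scipy (`scipy.optimize.milp`); no commercial solver is needed.

## Worked example

```r
library(tcosa)

## a catabolic/anabolic toy: NAD+-reducing glycolytic step, NADPH-consuming
## biosynthetic step, lumped regeneration, biomass consuming both pools
tc <- buildToyTcosa(toyRedoxFixtureSpec())
tc
#> TcosaModel: 10 irreversible reactions, 8 metabolites
#>   4 variant groups with >= 2 members; 1 dual-cofactor reactions
#>   pools: NAD, NADP; 9 thermo-active reactions

wt <- wildTypeAssignment(tc)
solveMdf(applyScenario(tc, wt), list(growthMin = 1))
#> MdfSolution (MDF): status optimal
#>   B = 19.7752 kJ/mol
#>   6 active reactions

## the wild-type specificity already attains the flexible optimum ...
flex <- solveMdf(applyScenario(tc, flexibleAssignment(tc)), list(growthMin = 1))
mdfValue(flex)
#> [1] 19.77516
minSwapsToTarget(tc, wt, mdfValue(flex), growth = 1)$count
#> [1] 0

## ... a single collapsed pool is markedly worse ...
mdfValue(solveMdf(applyScenario(tc, singlePoolAssignment(tc)), list(growthMin = 1)))
#> [1] 13.18344

## ... and at the optimum the NAD(H) pool must stay more oxidized than NADP(H)
ratioRange(tc, wt, growth = 1, objective = "MDF")
#> RatioRange (MDF at B = 19.7752, growth 1.000 h^-1):
#>   ratio in [4.625e-06, 0.0003436] (rho in [-12.2841, -7.9760])
```

The MDF of 19.78 kJ/mol means every reaction of the optimal flux distribution
can operate at least 19.78 kJ/mol downhill; the ratio interval says that at
this optimum the `[NADH]/[NAD⁺]` ratio must be 3×10³–2×10⁵ times smaller
than `[NADPH]/[NADP⁺]` — the familiar in vivo asymmetry of the two pools,
recovered from network structure and thermodynamics alone.

A thin command-line front end over the same functions ships in
`inst/scripts/tcosa` (subcommands `toy`, `prepare`, `fba`, `mdf`, `submdf`,
`sweep`, `random`, `swaps`, `ratio`, `three-cofactor`).

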