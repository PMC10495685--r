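# cardopt

Quality control for genome-scale metabolic models by cardinality
(zero-norm) optimization.

Constraint-based models are audited before use in flux balance analysis
(FBA): every internal reaction must conserve mass (**stoichiometric
consistency**: a strictly positive mass vector `ℓ` with `Nᵀℓ = 0` over the
internal columns `N`), every reaction must be able to carry a nonzero
steady-state flux (**flux consistency**: `Sv = b`, `l ≤ v ≤ u`, `v_j ≠ 0`),
and ideally every active flux must run against a chemical-potential
difference (**thermodynamic flux consistency**: `z_j > 0 ⇒ Nⱼᵀy < 0`).
Finding the *largest* consistent subsets, the *fewest* nonzero fluxes
attaining an FBA optimum, or the *fewest* constraints to relax in an
infeasible model are all cardinality problems

```
min / max  ‖x‖₀   subject to linear constraints,
```

NP-hard in general. `cardopt` approximates the step function inside `‖·‖₀`
with a continuous nonconvex surrogate — by default the capped-ℓ1 function
`ψ(t) = min{1, θ|t|}` — rewrites the objective as a difference of convex
functions, and solves it with a DC algorithm (DCA): a short sequence of
linear programs, each obtained by linearizing the subtracted convex
component at the incumbent. Six surrogate families are provided
(`cappedL1`, `exp`, `scad`, `log`, `lpPos`, `lpNeg`), an exact enumeration
oracle verifies the heuristic on small instances, and every consistency
verdict that can be certified exactly (mass certificates, per-reaction flux
LPs, chemical-potential certificates) is.

Built on top of that core:

* `find_stoich_consistent_subset()` — minimal mass-conservation relaxation
  with sequential omission of apparently elementally imbalanced (or most
  lumped) reactions,
* `find_leaks_siphons()` — metabolites producible from, or consumable to,
  nothing with the boundary closed,
* `find_flux_consistent_subset()` — exact blocked-reaction detection,
* `find_thermo_flux_consistent_subset()` — certified thermodynamically
  consistent subnetwork (an under-estimate, with re-verifiable witnesses),
* `sparse_fba()`, `relaxed_fba()`, `atp_cycle_test()` — minimum-support
  optimal fluxes, minimal constraint relaxation of infeasible models, and
  detection of stoichiometrically balanced cycles that admit isolated ATP
  hydrolysis,
* `full_audit()` — the whole pipeline, summarized as the usual
  model-comparison table row set,
* `make_consistent_network()` and the `inject_*()` defect generators —
  seeded synthetic networks with exact integer ground truth,
* readers/writers for SBML Level 3 FBC, cobrapy-style JSON, and TSV
  triplets; broom-style `tidy()`/`glance()` and `autoplot()` methods.

LPs are solved through a two-backend abstraction: `"highs"` (default,
HiGHS via a persistent SciPy worker process — requires a `python` with
`scipy` on the PATH) or `"dense"` (a pure-R two-phase simplex for small
instances); see `lp_backend()`.

## Worked example

Build a small consistent network, corrupt it with two mass-inconsistent
reactions and one blocked reaction, and audit it:

```r
library(cardopt)

fx <- make_consistent_network(m = 8, n_internal = 12, n_external = 4, seed = 1)
fx <- inject_inconsistency(fx, k = 2, seed = 1)   # adds BAD_* columns
fx <- inject_blocked(fx, k = 1, seed = 1)         # adds a dead-end reaction

full_audit(fx$model)
#> <audit_report>
#>   reactions                            21
#>   internal_reactions                   17
#>   stoich_consistent_rxns               15
#>   elementally_balanced_rxns            15
#>   omitted_rxns                         2
#>   stoich_and_flux_consistent_rxns      14
#>   stoich_not_flux_consistent_rxns      1
#>   ...
#>   FBA-ready: FALSE
```

Of the 17 heuristically internal reactions, 15 are stoichiometrically
consistent: the two corrupted columns were relaxed by the minimal
mass-conservation relaxation, found elementally imbalanced, and omitted
(`omitted_rxns: 2`). One consistent reaction cannot carry flux
(`stoich_not_flux_consistent_rxns: 1`) — the injected dead end. Because
inconsistent internal reactions remain, the model is not FBA-ready, and
with the boundary closed the corrupted columns let mass appear from
nothing, which the leak/siphon rows report.

Per-reaction labels are ordinary tibbles:

```r
tidy(find_stoich_consistent_subset(fx$model)) |> dplyr::count(label)
#> # A tibble: 3 × 2
#>   label                 n
#> 1 external              4
#> 2 omitted_unknown       2
#> 3 stoich_consistent    15
```

Sparse FBA on the same model (maximize export of metabolite `M008`):

```r
mdl <- fx$model
mdl$obj[match("EX_M008", mdl$rxn_ids)] <- 1
sparse_fba(mdl)
#> <sparse_fba: rho* = 1000, |support| = 3 (0 removable), 2 LPs>
```

The optimum is attained with only 3 active reactions, found in 2 linear
optimizations, and no support member can be removed without losing the
optimum.

A thin command-line interface over the same functions lives at
`inst/cli/cardopt.R` (`full-audit`, `check-stoich`, `leaks`,
`flux-consistency`, `thermo-consistency`, `sparse-fba`, `relax-fba`,
`atp-cycles`, `make-fixture`).

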