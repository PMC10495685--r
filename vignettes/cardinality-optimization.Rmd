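---
title: "Cardinality optimization for metabolic model quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardinality optimization for metabolic model quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardopt)
```

## The problem

A genome-scale metabolic reconstruction is a stoichiometric matrix $S \in
\mathbb{R}^{m \times n}$ (metabolites by reactions) together with flux
bounds $l \le v \le u$. Before such a reconstruction can be used for flux
balance analysis (FBA), several quality conditions must hold: every internal
reaction should conserve mass (*stoichiometric consistency*), every reaction
should be able to carry a nonzero steady-state flux (*flux consistency*),
and ideally every flux should be realizable against a chemical-potential
gradient (*thermodynamic flux consistency*). When they fail, one wants the
*smallest* set of offending constraints or reactions — and "smallest set"
questions are cardinality (zero-norm) optimization problems, which are
NP-hard in general.

This package approaches all of them through one device: the step function
$1\{t \neq 0\}$ inside $\|x\|_0 = \sum_j 1\{x_j \neq 0\}$ is replaced by a
continuous concave-in-$|t|$ approximation $\psi_\theta(t) \in [0,1]$, the
resulting nonconvex objective is split into a difference of convex (DC)
functions, and a DC algorithm (DCA) solves a short sequence of linear
programs. The default family is the capped-$\ell_1$ function
$\psi_\theta(t) = \min\{1, \theta\lvert t\rvert\}$, whose DC subproblems are
linear in both minimization and maximization mode.

## The DC machinery

Every family $\psi_\theta$ implemented here (`cappedL1`, `exp`, `scad`,
`log`, `lpPos`, `lpNeg`) is even, zero at the origin, nondecreasing in
$|t|$, concave as a function of $u = |t|$ with a finite slope $s_0$ at
$u = 0$, and converges pointwise to the exact step as $\theta \to \infty$.
Concavity in $u$ gives the generic split used for cardinality
*minimization*:

$$\sum_j \psi(t_j) \;=\; \underbrace{s_0 \sum_j |t_j|}_{\phi,\ \text{convex,
LP-representable}} \;-\; \underbrace{\sum_j \big(s_0 |t_j| -
\psi(t_j)\big)}_{\varphi,\ \text{convex}}.$$

DCA linearizes $\varphi$ at the incumbent via a subgradient and solves the
resulting LP; each step cannot increase the approximate objective, which is
the monotone-descent guarantee asserted throughout the test suite (at the
sharpness in force for that step; see *Sharpening schedule*). For
cardinality *maximization* the co-step sum $\sum_j (1 - \psi(t_j))$ is
decomposed instead; only the capped-$\ell_1$ family keeps the convex part
piecewise linear ($\phi = \sum_j \max(\theta |t_j|, 1)$), so the other five
families deliberately refuse maximization mode.

Absolute values enter the LP through epigraph variables ($a_j \ge \pm x_j$,
and $e_j \ge \theta\,|y_j|$, $e_j \ge 1$) rather than plus/minus splits. The
two formulations are equivalent, but the epigraph form makes it structurally
impossible for the LP to inflate a split pair and misreport a support.

### Initialization, sharpening, restarts, polish

* **Initialization.** The first LP minimizes the weighted one-norm of the
  minimized block — the convex $\ell_1$ relaxation. For maximized blocks,
  where the $\ell_1$ analogue is not convex, the first LP instead rewards
  each variable in the direction with more bound headroom, with a seeded
  jitter wide enough to flip the preferred direction of reversible
  variables between restarts. The initialization LP clips cardinality-block
  bounds at $\pm 10^4$ so the directional reward cannot be unbounded.
* **Sharpening schedule.** $\theta$ starts at $0.5$ and is multiplied by
  $1.5$ each outer iteration, capped at $10^3$. Progressive sharpening first
  lets the $\ell_1$ geometry pick a basin, then hardens the approximation.
  The iteration stops when the support sets are unchanged and the
  approximate objective moved by less than `tol` ($10^{-6}$).
* **Restarts.** DCA is a local method. `solve_cardinality()` therefore runs
  a small number of seeded starts (default 3; the later ones randomize the
  $\ell_1$ weights and start sharper) and keeps the start with the lowest
  exact weighted cardinality. `sparse_fba()` overrides this to a single
  start, because its point is precisely that one capped-$\ell_1$ run needs
  only two or three LPs even at genome scale — and the mid-size experiments
  in the test suite confirm 2–3 outer LPs.
* **Polish.** A found support is post-processed by one-at-a-time
  removability: a member is dropped when the problem stays feasible with
  that member and all off-support block variables fixed to zero. The result
  is locally minimal by construction. Removability is always assessed
  *within* the support: with the whole network free, any alternative route
  makes a member look removable even when the support has minimum size.

### Support reading and tolerances

Supports are read at $\varepsilon_{\text{supp}} = 10^{-6}$, matching the
feasibility tolerance of double-precision LP solvers; claiming more
resolution than the solver has would manufacture phantom nonzeros. The same
tolerance zeroes relaxations in `relaxed_fba()` and reads fluxes in the
consistency routines.

### LP backends

All LPs go through a two-backend abstraction: `"highs"` (default) sends
batches of problems over a pipe to a persistent worker process running the
HiGHS solver, and `"dense"` is a small two-phase tableau simplex with
Bland's anti-cycling rule implemented in the package, used for small
instances and for backend-agreement tests. Tie-breaking among alternative
LP optima is the backend's; results are backend-reproducible rather than
backend-independent, and tests that depend on exact supports pin the
backend. Neither backend accepts a warm-start basis, so the speed-up
available from warm-starting consecutive DCA subproblems is not exploited;
this affects runtime only, never the iterates.

## The six applications

**Stoichiometric consistency** asks for a strictly positive mass vector
$\ell$ with $N^\top \ell = 0$ over the internal columns $N$. Instead of
maximizing the number of conserved metabolites, the package minimizes the
number of *relaxations*: $\min \|x\|_0$ s.t. $N^\top w + x = 0$, $w \ge 1$.
Reactions needing no relaxation are consistent. Because a reaction of
undetermined consistency can become consistent once another suspect is
removed, the procedure is sequential: after each solve, the relaxed
reactions that are also apparently elementally imbalanced (or, lacking
formulae, those with the most nonzero coefficients — lumped reactions) are
omitted, and the relaxation is recomputed until its cardinality stops
decreasing. Under the elemental criterion the relaxation weights of
apparently imbalanced reactions are halved, so that among equally small
relaxation supports the solver blames the reactions the omission criterion
targets; the final consistent set is always re-certified by an exact
feasibility LP, so this bias can never produce a false "consistent" label.
Stoichiometric consistency is invariant to the flux bounds, and the tests
assert exactly that.

**Leak/siphon testing** closes the exchange reactions and maximizes the
cardinality of a production vector $y \ge 0$ with $Sv - y = 0$ (leaks;
$Sv + y = 0$ for siphons). The DCCO solve finds the bulk in one shot; every
remaining metabolite is then settled exactly by a single LP maximizing its
production, so the reported sets are exact, not heuristic. A
minimal-cardinality flux mode leaking a chosen metabolite normalizes the
leak rate to $\ge 1$ to remove scale degeneracy.

**Flux consistency** amalgamates supports of repeated cardinality
maximizations over not-yet-covered reactions, then settles the remainder
with the per-reaction pair of LPs ($\max v_j$, $\min v_j$). The final set is
exact and equal, by construction and by test, to the $2n$-LP oracle; DCCO
only reduces how many of those LPs are needed.

**Thermodynamic flux consistency** (the one genuinely nonconvex problem)
uses a propose–project–certify loop: a candidate flux from cardinality
maximization is projected onto a cycle-free flux with the same exchange
pattern by minimizing a weighted one-norm of the internal flux under sign
restrictions (any strictly positive weights remove sign-concordant cycles;
uncovered reactions get weight 0.01 so equivalent routes favor them), and
the resulting sign pattern is certified by the potential LP
$\sigma_j (N_j^\top y) \le -1$. When certification fails, the LP's
infeasibility has a dual witness — a sign-concordant internal cycle — whose
reactions are deactivated before re-projection. Exactly one of the two
certificates exists (a theorem-of-the-alternative argument, asserted on
random instances), and every reported reaction carries a re-verifiable
$(v, y)$ witness. Because the feasible set is nonconvex the amalgamated set
is an *under*-estimate: a reaction outside it is "not certified within the
budgeted rounds", not proven inconsistent. The potential inequality is
normalized to $\le -1$ since potentials are scale-free.

**Sparse FBA** minimizes $\|v\|_0$ subject to attainment of the FBA optimum
$\rho^\star$, implemented as $c^\top v \ge \rho^\star - 10^{-6}$ so the
attainment test matches what a double-precision solver can distinguish.
**Relaxed FBA** minimizes $\lambda\|r\|_0 + \alpha\|p\|_0 + \alpha\|q\|_0$
over $Sv + r = b$, $l - p \le v \le u + q$; steady-state relaxation is
off by default because relaxing mass balance conceals stoichiometric
errors, and $r$ is treated sign-free so that either direction of imbalance
can be repaired. The returned relaxation is applied and re-verified
feasible before it is reported. The **isolated ATP hydrolysis test** closes
the boundary, forces at least unit flux through the hydrolysis reaction and
minimizes internal support; a finite answer exposes a stoichiometrically
balanced cycle whose bounds admit free energy generation, and converting
one member to irreversible against the cycle removes it.

## What the synthetic generator emulates — and what it does not

`make_consistent_network()` builds networks whose internal part satisfies
$N^\top \ell = 0$ *exactly in integer arithmetic*: integer masses in 1–4, a
connected chain backbone, extra pair/triple reactions, coefficients bounded
by $\pm 4$, exchange columns with single $-1$ entries, and formulae
$\mathrm{C}_{\ell}\mathrm{H}_{2\ell}$ that encode the masses so elemental
imbalance coincides with mass imbalance by construction. Defect injectors
add, with ground truth: mass-inconsistent columns (guarded by a duplicated
parent column so the corrupted column is the unique minimal relaxation),
blocked dead-end reactions, balanced internal loops whose bounds admit
circulation, and forced-flux conflicts with known minimal repair
cardinality. Default sizes are `tiny` (6 metabolites, 8 internal reactions)
for unit tests and `mid` (300 metabolites, 500 internal + 60 exchange
reactions) for the scaling experiments; these sizes were chosen once as the
smallest scales at which the iteration-count claims are meaningful.

What the fixtures do *not* emulate: realistic degree distributions,
compartments, cofactor coupling, thousands of metabolites, curation noise
in formulae, or the block structure of real reconstructions. Passing tests
therefore demonstrate algorithmic correctness (oracle agreement, exactness
of the LP-settled sets, certificate validity, invariances) — they do not
demonstrate that the heuristic components (DCCO support quality, thermo
coverage) behave identically on published human reconstructions, where the
published comparisons must be reproduced with `full_audit()` on the
downloaded models.

## Degenerate inputs and edge cases

All-zero reaction columns are flagged external with a warning. Metabolites
with missing or pseudo-element formulae (R groups, `X`, `*`) make their
reactions *undetermined*, never "balanced". An empty internal set is
vacuously consistent. Cardinality-block entries with zero weight move to
the free block. Excluding a variable whose bounds forbid zero from a
support is recognized as infeasible without an LP call. The brute-force
oracle refuses more than 20 enumeration variables.

## Known limitations

* DCCO is a local heuristic: on ~5% of random small instances it reports a
  support one larger than the optimum (never smaller — that is
  structurally impossible and tested). More restarts shrink but cannot
  close this gap.
* The thermodynamic subset is an under-approximation with a round budget;
  the logarithmic step family converges to the exact count only at rate
  $1/\log\theta$; warm starts are unavailable through the LP backends.
* The internal/external split is heuristic (single-nonzero columns plus an
  id-prefix list) and tends to under-count external reactions; it is
  configurable where reconstruction conventions differ.
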