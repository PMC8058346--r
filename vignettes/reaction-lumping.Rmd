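---
title: "Reaction lumping for thermodynamic flux analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction lumping for thermodynamic flux analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why lump reactions

Thermodynamic metabolic flux analysis (TMFA) couples every reaction's flux
to the sign of its Gibbs free energy change,

$$\Delta G_j = \Delta G^0_j + RT \sum_i s_{ij} \ln x_i,
\qquad
\Delta G^0_j = \sum_i s_{ij} \Delta_f G^0_i,$$

so a reaction may only carry flux while $\Delta G_j < 0$. The catch is data
coverage: when any participating metabolite lacks a standard Gibbs free
energy of formation $\Delta_f G^0$ (kJ/mol), $\Delta G^0_j$ is undefined and
the reaction escapes thermodynamic constraint entirely. Reaction lumping
recovers constraints for such regions: a *lumped reaction* is a nonnegative
linear combination $y = R\alpha$ of the undetermined reactions in which
every unknown-$\Delta_f G^0$ metabolite nets to exactly zero. Its
$\Delta G^0$ is then computable from the known metabolites alone, and the
lump is added to the TMFA program as constraints only — it has no flux
variable, so the steady-state flux space is untouched. An infeasible lump
forces at least one of its member reactions off through the binary coupling
$\sum_j \alpha_{kj} z_j \le \sum_j \alpha_{kj} - (1 - y_k)$.

## The lumping program

Given the reduced matrix $R$ (all metabolites appearing in the undetermined,
lump-eligible reactions, by those reactions) and a target set $U$ of
unknown metabolites, the package solves

$$\min_{\alpha, y^+, y^-} \sum (y^+ + y^-)
\quad \text{s.t.} \quad
R\alpha = y^+ - y^-, \quad
y_u = 0 \;\forall u \in U, \quad
\alpha^{\min} \le \alpha \le \alpha^{\max},$$

where $\alpha^{\min}_j = 1$ for every column $j$ containing a *seed*
metabolite and $0$ otherwise. Minimising the total absolute stoichiometry
(the classical $y^+/y^-$ variable split) keeps lumps small and sparse.
Infeasibility is informative, not exceptional: it certifies that the seeds
cannot be eliminated together.

Three procedures are layered on this program:

* **group**: one LP per group with $U$ = seeds = the whole group;
* **sequential**: per seed $u$, start from $U' = \{u\}$; whenever the
  optimal lump still involves other unknown metabolites, move one of them
  into $U'$, append the interim solution $y$ as an extra column of the
  working matrix, and re-solve; abandon the seed on infeasibility;
* **combined**: group first, sequential fallback per group. Groups are the
  connected components of the bipartite unknown-metabolite/reaction graph,
  and are provably independent: no eligible reaction touches unknown
  metabolites of two groups, which is what licenses solving them in any
  order (a property the test suite exercises).

### Design choices the formulation leaves open

Several details are under-determined by the formulation itself; the package
resolves them as follows and treats them as part of its contract.

* **Seed-constraint scope.** $\alpha^{\min}_j = 1$ is applied only to
  columns containing a *seed* (the group members in group mode; the single
  starting metabolite in sequential mode). Metabolites added to $U'$ during
  the iteration are constrained to zero but do not force their columns into
  the combination. The alternative reading (forcing columns of every $U'$
  member) would make the sequential walkthrough on the packaged toy network
  impossible: the accepted lump r4 + r5 + r6 for seed G keeps
  $\alpha_{r3} = 0$ even though the drawn-in metabolite H participates in
  r3.
* **One metabolite per iteration.** When an interim solution involves
  several new unknown metabolites, exactly one — the one with the smallest
  model index — joins $U'$. This makes LP counts deterministic.
* **No skipping.** Sequential mode processes every seed, including
  metabolites already eliminated by earlier seeds' lumps; LP counts include
  infeasible solves. Failed seeds leave no trace: working-matrix
  augmentations are discarded, and accepted lumps are *not* added to $R$
  for later seeds (they contain no unknown metabolite, so they cannot help
  eliminate one).
* **Continuous $\alpha$.** The program is solved as an LP by default, with
  `integer = TRUE` available; the toy fixture verifies identically under
  both. Alternative optima are not enumerated — the first solver optimum is
  taken, so eliminated sets are stable but per-seed LP counts can in
  principle differ between solvers on degenerate instances. The packaged
  toy network is engineered so its optima are unique and the counts forced.
* **Split-direction degeneracy.** Both directions of a split reversible
  reaction enter $R$ as separate columns (the nonnegativity of $\alpha$
  requires direction-explicit columns). A support containing both
  directions of one reaction is a null combination invisible to the
  objective; recorded lumps subtract $\min(\alpha_{fwd}, \alpha_{rev})$
  from both.
* **"Eliminated" metabolites.** A group-step success eliminates all group
  members; a sequential-step success eliminates its seed. Metabolites that
  merely happen to net to zero in someone else's lump are not counted —
  their own seeds may still fail, and the per-seed attribution is what the
  LP-count bookkeeping refers to.
* **Lump-eligible reactions.** Biomass and exchange reactions are excluded
  from $R$ (the biomass reaction is synthetic, and blocking it through an
  infeasible lump would be catastrophic; exchanges are weakly evidenced).
  Internal transport reactions are eligible by default and can be excluded
  with `include_transport = FALSE`.

## The TMFA program

`build_tmfa()` assembles the MILP: steady state $Sv = 0$ over model
reactions, flux bounds, log-concentration variables with configurable
bounds, a $\Delta G$ variable and binary $z_j$ for every determined
internal reaction with the coupling $v_j \le z_j v^{max}_j$ and
$\Delta G_j \le (1 - z_j)M - \varepsilon$, and for every lump the
constraints above. The model-reaction coupling is the standard TMFA
formulation; the strictness margin $\varepsilon$ implements "strictly
negative". Exchange and biomass reactions carry flux but no thermodynamic
constraint: their $\Delta G$ is not meaningful (exchanges are
pseudo-reactions across the system boundary), which is also standard TMFA
practice. Undetermined model reactions get a $z_j$ (and the flux coupling)
only when they are members of some lump.

`dG_variability()` minimises and maximises every $\Delta G$ variable
subject to the full MILP with biomass held at a fraction (default 0.9) of
the FBA optimum, and classifies a reaction irreversible exactly when its
maximum $\Delta G$ is strictly negative ($\Delta G_{max} = 0$ counts as
reversible). Adding lumped-reaction constraints can only shrink these
ranges and can only lower the TMFA optimum — both monotonicity properties
are asserted on random models in the test suite.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| temperature | 298.15 | K | standard conditions; the $RT$ term scales exactly linearly in $T$ |
| gas constant | 8.314e-3 | kJ/(mol K) | fixed physical constant |
| concentration bounds | 1e-6 – 2e-2 | mol/L | the conventional 1 µM – 20 mM physiological window |
| `big_m` | 1000 | kJ/mol | must dominate $|\Delta G^0| + RT \ln(\text{hi}/\text{lo})$; at the default bounds the log span is ~24.5 kJ/mol |
| `biomass_fraction` | 0.9 | — | variability at 90% of the FBA optimum |
| `epsilon` | 1e-6 | kJ/mol | strict negativity margin for active reactions |
| `alpha_max` | 1000 | — | boundedness of the lumping LP; never binding on desk-scale systems |
| zero tolerance | 1e-9 | — | nonzero detection on solver floats (configurable) |
| `time_limit` | 120 | s | per-MILP cap; hitting it raises a warning, never a silent truncation |

Per-metabolite concentration relaxations are supported
(`tmfa_config(conc_overrides = ...)`) but never applied silently;
`ijr904_relaxations()` documents a published example set for *E. coli*
(glycerophosphoglycerol, glycerophosphoethanolamine, cytosolic water, and
NADH). When the variability base problem is infeasible the error message
points at this mechanism.

All thermodynamic inputs are standardised on kJ/mol; annotation files in
kcal/mol must be converted before loading (a deliberate single-unit policy,
since annotation provenance varies).

## Fixtures: what they emulate and what they do not

`make_fig1_toy()` reconstructs a small network around a fixed
unknown-metabolite core: two groups, one eliminable at once
({A, B} via r1 + r2 + r7) and one only partially eliminable
({E, G, H}, where only G falls to r4 + r5 + r6). The unknown-row submatrix
over r3–r6 is fixed; the known-metabolite ("filler") coefficients are
frozen constants found once by bounded integer search so that every LP in
the sequential walkthrough has a unique, forced optimum (3 + 2 + 3 = 8 LPs
over the second group, 2 LPs per seed over the first). `verify_fig1_toy()`
re-derives the entire trace against the live solver — with continuous and
with integer coefficients — so the fixture cannot silently drift.

`make_synthetic_gem()` produces random annotated models: a linear pathway
backbone (uptake → chain → biomass) guarantees a nonzero FBA optimum, and
sparse random "noise" reactions create intertwined unknown-metabolite
groups. Formation energies are drawn from Normal(−300, 200) kJ/mol and
assigned in decreasing order along the backbone so the chain is
thermodynamically realisable within the default concentration window;
a configurable fraction of metabolites then loses its annotation.
Generation is a pure function of the seed.

What passing tests on these fixtures shows: the procedures implement the
stated programs (verified against an exhaustive integer-grid oracle on
systems with up to 5 columns and coefficients up to 3), the group/
sequential/combined bookkeeping is exact, and the TMFA constraint algebra
has the right monotonicity and closed-form behaviour. What it does not
show: performance or elimination yields on real genome-scale models, whose
group-size distributions, compartmentalisation, cofactor structure and
annotation biases the generator does not emulate. Problem sizes in the
default suite are deliberately small — tens of metabolites and reactions,
LP batteries of a few dozen programs — so the whole suite runs in a few
minutes on one CPU.

## Numerical notes

* The LP/MILP backend is HiGHS via scipy, driven through a batched JSON
  bridge; independent solves (e.g. all variability min/max programs) are
  submitted in one batch. Solver infeasibility is a first-class return
  value, distinguished from numerical failure.
* The variability analysis can cap $\Delta G_{max}$ at $-\varepsilon$ for
  reactions forced active by the biomass constraint; ranges for optional
  branches are unconstrained by the coupling and match the closed form — for
  a one-substrate, one-product reaction,
  $\Delta G^0 \pm RT \ln(\mathrm{hi}/\mathrm{lo})$ (tested to 1e-5 kJ/mol).
* Degenerate inputs: an all-determined model yields an empty reduced system
  and zero LPs; an empty group list yields an empty run; a metabolite
  occurring in exactly one eligible reaction can never be eliminated (the
  forced $\alpha \ge 1$ contradicts the zero constraint) and its group LP
  returns infeasible.
* Sequential iterations are capped (default 50 per seed); exceeding the cap
  names the seed rather than looping.

## Known limitations

* No enumeration of alternative optima and no backtracking: the procedure
  eliminates a max*imal*, not max*imum*, set of metabolites — the
  first-found lump per seed is kept.
* The membrane-transport $\Delta G^0$ adjustment for cross-compartment
  lumps is a pluggable hook (`transport_adjustment`); the default warns and
  applies no correction, since no universally applicable formula exists
  without membrane-potential and pH parameters.
* No pH/ionic-strength transforms of $\Delta_f G^0$, and no estimation of
  missing values (group-contribution methods are out of scope); the package
  consumes annotations as given.
* Reversibility tallies on real models depend on the annotation files,
  per-metabolite relaxations and solver tie-breaking; the package asserts
  the structural properties (nestedness of ranges, the strict-negativity
  rule) rather than reproducing any published tally.
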