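---
title: "How many Lennard-Jones types does a force field need? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How many Lennard-Jones types does a force field need? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ljtyping)
```

## The problem

Classical force fields model van der Waals interactions with a 12-6
Lennard-Jones (LJ) term,

$$E_{LJ,ij} = \varepsilon\left[\frac{r_{min}^{12}}{r^{12}}
  - \frac{2\,r_{min}^{6}}{r^{6}}\right],\qquad
\varepsilon = \sqrt{\varepsilon_i\varepsilon_j},\qquad
r_{min} = r_{1/2,i} + r_{1/2,j},$$

where every atom is assigned to an *LJ type* — an equivalence class sharing
one $(\varepsilon, r_{1/2})$ pair — and unlike pairs combine by the
Lorentz-Berthelot rules above. Historically, type catalogues grew by
chemical intuition; this package implements a data-driven pipeline for
asking how few types suffice: typing models expressed as ordered SMIRKS
rules, a regularized property-matching objective, local optimization with
multi-start diagnostics, a greedy type-splitting search, and a scaled
parameter-space distance analysis, all runnable at desk scale on a
synthetic stand-in for molecular dynamics.

## Typing models

A typing model is an ordered list of one-tagged-atom SMIRKS rules in
ascending priority. Assignment is *last-match-wins*: the general element
pattern (for example `[#6:1]`) assigns first, and later, more specific
patterns (for example `[#6X4:1]`) overwrite it, so every atom of a covered
element always ends with exactly one type. Model names follow an
element-count grammar — `HCON` has one type per element, `H2CO3N` splits
hydrogen into polar/apolar and oxygen into carbonyl/hydroxyl/ether — and
`typing_model()` assembles the rule list from published building blocks, so
user-defined combinations are constructible. Priority ties are impossible
by construction: list position *is* the priority.

Two typeset glitches in the published rule table are resolved in favour of
the SMIRKS strings over their prose labels: the `[#1:1]-[#7]` row
(described as H-on-oxygen) matches hydrogen on nitrogen, and
`[#8X2H0+0]` (labelled alcohol) matches an oxygen with no attached
hydrogen, i.e. an ether. Our type ids name what the patterns match. The
sp2-hydrogen rule is widened to `[#1:1]-[#6X3,#6X2]` so hydrogens on sp
carbons receive the specific rule rather than the fallback; pass
`sp_carbon_h = FALSE` for the strictly published pattern. Because every
element needs a lowest-priority general rule *and* the type count must
equal the model-name digits, fallback rules may share the type id of one
specific rule (the H4 block's `[#1:1]` fallback shares the sp3-H type).

The 15-type `SmirFF` skeleton (8 H, 3 C, 3 O, 1 N over CHON liquids) is a
synthetic stand-in: the exact source force field's rule list is not
shipped here, so the skeleton's SMIRKS are plausible reconstructions and
are documented as such.

No cheminformatics toolkit is available in the target R stack, so the
package carries a restricted CHON SMILES reader (organic subset, branches,
ring closures, explicit-H expansion with a stable, documented atom order)
and a SMIRKS-primitive matcher covering exactly the vocabulary the rules
use (`#z`, `X`, `H`, formal charge, one- and two-bond paths). Partial
charges are *inputs*, never derived.

## The objective

Training minimizes

$$L(\mathbf{k}) = \sum_{m=1}^{M} L_m(\mathbf{k})
  + w_{reg}\,\lvert\mathbf{k}\rvert^2,\qquad
L_m = \sum_p \frac{\lvert y_p^m - y_{p,ref}^m\rvert^2}{d_p^2},$$

with denominators $d_{density} = 95$ kg/m³ and $d_{HOV} = 0.95$ kJ/mol and
$w_{reg} = 0.1$. Physical parameters enter through the affine transform
$k_i = (K_i - K_i^0)/t_i$ with prior widths $t = 0.1$ kcal/mol for
$\varepsilon$ and $1.0$ Å for $r_{1/2}$, so the restraint is a Tikhonov
penalty on displacement from the starting values. Training uses density
and heat of vaporization; the dielectric constant enters evaluation only,
with a deliberately large configurable denominator (default 10), because
its estimates are the noisiest. Test-set objectives are displayed scaled
(1/15 for split design 1, 1/3 for design 2) purely in the report layer —
a monotone transform that cannot change rankings, which a test asserts.

## Optimization

The optimizer is a damped Gauss-Newton (Levenberg-Marquardt with
curvature-scaled damping) on the scaled residual vector in k-space, with
central finite-difference Jacobians (step $10^{-3}$), evaluation caching,
and plain gradient descent as a fidelity option. Termination follows the
historical protocol: stop when the k-step norm falls below 0.01 or the
objective changes by less than 1.0 between accepted iterations. "Step
size" is interpreted as the Euclidean norm of the accepted k-step. Final
well depths are projected onto $\varepsilon \ge 0$; backends treat
negative trial values as zero, so the projection never changes the
objective. Non-finite trial points are rejected by the damping loop rather
than aborting; only a non-finite *starting* objective aborts.

`multi_start()` runs seeded replicates (three by default) and flags the
best-by-training-objective replicate, reporting the replicate range.
`consistency_check()` implements the superspace reality check: a model
whose types refine another's can never, at a true optimum, have a worse
training objective; a violation is diagnosed as under-optimization and the
coarse optimum embedded into the fine model (`embed_params()`) is returned
as a restart point, with the embedded values becoming the new restraint
center — matching the reoptimization-from-alternative-start protocol.
`greedy_split_search()` locks in the single-element split with the largest
held-out improvement each round, stopping when no candidate clears a
configurable margin; it is greedy by construction, and a test demonstrates
the classical failure mode where two splits help only jointly.

## The synthetic world

The real study computes properties by NPT molecular dynamics of 700-copy
liquid boxes; that is far outside desk scale, so `make_study()` builds a
synthetic stand-in with three committed ingredients.

**Library.** Templated SMILES generators over eight functional-group
classes (alkanes, alkenes, ethers, alcohols, ketones/aldehydes, esters,
amines, nitriles), cycled so any prefix spans all classes; 75 compounds by
default, mirroring the original collection's size and split designs
(15/60 class-covering and 30/45 random). Amine templates span primary,
secondary and tertiary amines: the N-H count contrast (2/1/0 per nitrogen)
is the only chemical signal separating polar-hydrogen parameters from
amine-nitrogen parameters under the oracle below, and real training sets
contain tertiary amines too. Charges are fixed per functional group and
neutralized per molecule; charge derivation is out of scope.

**Oracle.** A deterministic, smooth, type-separable map from per-atom
assigned parameters to properties:
density $= c_\rho M / \sum_a r_a^3$,
HOV $= c_h \sum_a \sqrt{\varepsilon_a}\, r_a^3 + c_p\, n_{pairs} + RT$,
dielectric $= 1 + c_d (n_{polarH} + n_O + n_N)^2 / \sum_a r_a^3$, with
constants $c_\rho = 700$, $c_h = 1.5$, $c_p = 6$, $c_d = 180$ fixed once so
outputs land in realistic organic-liquid ranges (roughly 600-1150 kg/m³,
12-50 kJ/mol, 1-70). Monotonicity and type-separability are tested
properties. Optional Gaussian noise uses the stated simulation
uncertainties: 1 kg/m³ density, 0.3 kJ/mol HOV, 10% relative dielectric.

**Ground truth.** The published optimized H2CO3N parameter column, with
the three oxygen rows shrunk 40% toward their common mean. This encodes,
deliberately, the qualitative ordering reported for real liquids: the
polar/apolar hydrogen split (half-radii 0.88 vs 1.42 Å) is the dominant
signal, the oxygen split is real but second, and carbon-hybridization and
nitrogen splits are property-neutral because the truth assigns them single
values. Without the shrink the oxygen split out-gains the hydrogen split,
inverting the stated ordering — the one revision made to the original
truth choice, recorded here and in the project notes.

What a green test on this world establishes: that the typing, objective,
optimizer, diagnostic and comparison machinery behave as specified on data
whose generating process is known. What it does not establish: anything
about absolute property accuracy of real liquids, for which the oracle is
no substitute.

### Benchmark protocol choices

The parameter-recovery benchmark runs with $w_{reg} = 0$ and tight
tolerances ($10^{-6}$), not the training protocol's $w_{reg} = 0.1$ and
coarse stop rules. Two measured reasons. First, at the stated noise the
whole data term is $O(8)$, so a restraint toward starting values that sit
far from the truth displaces the optimum by up to ~0.1 kcal/mol in well
depth — an estimator bias, not an optimizer property; the original
setting's data term is $O(100)$, where the same restraint is genuinely
weak. Second, the objective-change-below-1.0 stop rule is calibrated to
that $O(100)$ scale and would halt far from convergence here. The
benchmark also uses triplicate multi-start with 0.1 start jitter in
k-space: single starts demonstrably land in genuine local minima of even
this smooth surrogate surface — the same pathology the study documents for
the real fitness surface. The greedy-search benchmark runs on the
noise-free oracle with margin 0.1, using the margin exactly as designed:
to reject improvements below numerical significance.

## The toy liquid simulator

`run_toy_liquid()` is a rigid-molecule NPT Metropolis Monte Carlo engine
(C++ core): one idealized conformer per molecule (built-in bond lengths,
coordination-based angles, seeded dihedrals), minimum-image atom-atom LJ
plus truncated Coulomb inside a cutoff, analytic LJ tail correction, and
log-volume barostat moves with the $(N{+}1)\ln V$ Jacobian weight
attempted every 25 sweeps by default. The gas phase of a rigid conformer
is its constant intramolecular nonbonded energy (pairs three or more bonds
apart), so HOV reduces to the intermolecular energy per molecule plus
$RT$. Design consequences, documented loudly:

- Rigidity replaces flexible MD with bonded terms. The package's
  acceptance surface is the optimization and comparison machinery, not
  absolute property accuracy.
- Plain Coulomb truncation (no Ewald, no reaction field) biases dielectric
  estimates; they are qualitative. The fluctuation formula is the
  mean-subtracted conducting-boundary variant, switchable because the
  source does not state which variant was used.
- Defaults (100 molecules, 2×10⁵ + 10⁶ moves) run in minutes; the
  original scale (700 molecules, nanoseconds of MD) is representable in
  config but out of test scope.
- Energy bookkeeping is incremental with a full recomputation check
  (agreement to $10^{-8}$ relative is an acceptance criterion); runs are
  bit-reproducible by seed.
- The ideal-gas acceptance run starts at the ideal volume via the
  `init_volume` override: a dense cold start cannot random-walk a 400-fold
  volume expansion within desk-scale move budgets.

## Model distances

Every model is projected onto a common 12-row SMIRKS layout (4 H, 3 C,
2 N, 3 O environments, chosen by probe molecules typed under the model),
duplicated rows carrying duplicated values. A model is then a point in 24
dimensions (12 half-radii, then 12 well depths scaled by the ratio of the
mean half-radius to the mean well depth over all rows of all models —
13.69, printed as 13.7, for the packaged fixtures). Plain Euclidean
distances between these points reproduce all ten published pairwise
distances to ±0.01, and the nearest-neighbor structure recovers the
published reading: the trapped seven-type optimum sits closest to the
split-hydrogen model, while its reoptimized variant sits closest to the
split-oxygen model it was restarted from. The per-display-row duplication
convention is the one that reproduces the published numbers; per-unique-
type expansion does not and is not offered.

## Numerical conventions

Internal units are fixed (ε kcal/mol, lengths Å); HOV is reported in
kJ/mol and density in kg/m³, with 4.184 J/cal applied only at module
boundaries. Tie-breaks: `nearest_neighbor()` returns all tied models;
greedy acceptance requires strict improvement beyond the margin. Degenerate
inputs (empty compound lists, zero reference values, missing properties)
follow the documented contracts: defined type counts, exclusion with a
warning, and property skipping respectively.

## Known limitations

- The SMILES/SMIRKS machinery covers the CHON organic-liquid scope plus
  the documented primitives only; it is not a general toolkit.
- Aromatic perception trusts the input's lowercase flags with a simple
  implicit-H rule; fused or charged aromatics are outside validated scope.
- The toy simulator's dielectric estimates are biased by truncation;
  greedy and recovery benchmarks therefore run on the surrogate backend.
- The oracle's polar-hydrogen well depth is weakly identified (its HOV
  weight $\sqrt{\varepsilon}\,r^3$ is small at small radii) — an honest
  echo of the original study, where hydrogen well depths swing widely
  between equally good optima.
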