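---
title: "Ant-colony docking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant-colony docking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acodock)
```

## The optimization model

A docking pose of a flexible ligand in a rigid receptor is a vector
$x = (x_1, \dots, x_n)$ with $n = 3 + 3 + n_{rot}$: three centroid
translations (Å) bounded by the docking sphere's bounding box, three
Z–Y–Z Euler orientation angles on $[0, 360)$ degrees, and one torsion
angle per rotatable bond. The objective $f(x)$ is the scoring function;
the search seeks its global minimum.

Each degree of freedom is partitioned into intervals
$a_i = z_{i0} < z_{i1} < \dots < z_{in_i} = b_i$. `assign_interval()`
realizes the characteristic function: a value belongs to the interval
$[z_{i\ell-1}, z_{i\ell}]$ containing it, with boundary ties resolved to
the lower-indexed interval (the closed intervals overlap at shared
endpoints, so a convention is required) and $x_i = a_i$ mapped to
interval 1. On the unit partition of $[0,360]$, the value 1.7 falls in
interval 2.

Ants select interval $\ell$ for dof $i$ with probability
$\tau_{i\ell}/\sum_k \tau_{ik}$ and then draw the continuous value
uniformly **within** the chosen interval. Pure interval representatives
(upper bounds or midpoints) would confine the search to a lattice;
uniform-within-interval keeps it continuous while the discretization
still structures the learning. A `midpoint` sampling mode exists solely
so that grid-comparison oracles are exact.

Sampled poses are refined by an in-package Nelder–Mead simplex
(reflection 1, expansion 2, contraction 0.5, shrink 0.5) under an
explicit evaluation budget. The initial simplex displaces each dof by
$\sigma \cdot (b_i - a_i)/n_i$ — $\sigma$ interval widths — which is this
package's reading of the `aco_sigma` parameter (its exact semantics are
not derivable from the published description; a simplex scale is the
natural fit for presets in the 0.25–1.25 range). Rotational components
are wrapped modulo 360 and translations clipped to the box before every
evaluation, and the refined solution never scores worse than its start
point. `stats::optim`'s simplex is used in the test suite as an
independent reference, never as the implementation, because it exposes
neither an initial-simplex scale nor an evaluation budget.

The trail update is
$\tau_{i\ell} \leftarrow (1-\rho)\,\tau_{i\ell} + 1_{i\ell}\,\Delta\tau$
with $\Delta\tau = |f(s_a)|$ when the iteration-best refined solution
scores below zero, else no deposit. The indicator window spans the
solution's interval plus two neighbors either side for rotational dofs
(wrapping at 0/360) and one either side for translations (clipped at the
box). Only the iteration-best ant deposits, in the MAX-MIN ant-system
lineage; the bounds are $\tau_{max} = \Delta\tau_{best}/\rho$ (a running
estimate — the fixed point of the update under repeated reinforcement)
and $\tau_{min} = \tau_{max}/(2 n_i)$, with $\tau_0 = 1$ uniform before
any deposit. When $\rho = 0$ the bounds stay at their initial values
(the fixed-point formula is undefined), so deposits accumulate
unclamped; this degenerate setting is supported for testing only.

## Tunable parameters

| parameter | units | default | role |
|---|---|---|---|
| `search_speed` | 1, 2, 4 | 4 | divides the iteration budget: `ceiling(100/speed)` iterations |
| `aco_ants` (`n_ants`) | count | 20 | poses sampled per iteration |
| `aco_evap` (`rho`) | fraction/iter | preset | evaporation rate |
| `aco_sigma` (`sigma`) | interval widths | preset | initial simplex edge per dof |
| `ls_budget` | evaluations | 60 | simplex refinement budget per ant |
| `stagnation` | iterations | 15 | early stop after this many non-improving iterations |
| `angular_step` | degrees | 1 | rotational discretization (must divide 360) |
| `linear_step` | Å | 0.5 | translational discretization |
| `bindingsite_radius` | Å | 13 | docking sphere radius |

The preset table resolved by `resolve_defaults()` ties `rho` and `sigma`
to the scoring function and speed (chemplp 4/2/1 → ρ 0.15/0.20/0.20 and
σ 0.25/0.5/1.25; plp 4 → 0.20/0.5; plp95 4 → 0.20/1.25; 20 ants
throughout). Presets exist only for those combinations; anything else is
a configuration error rather than a silent guess. One published
statement describes the default sphere as 13 Å radius and another as
13 Å diameter; the radius reading is used here.

## Scoring

The pair potential is piece-wise linear in the interatomic distance $r$:
$w_{clash}(A-r)$ below $A$, linear from 0 at $A$ to the well depth at
$B$, flat on $[B, C]$, linear back to 0 at $D$, zero beyond — continuous
everywhere. Hydrogens are excluded from pair sums (heavy-atom
potentials); they enter only hydrogen-bond geometry. Pairs of
polar heavy atoms (donors/acceptors) use a shorter-range, deeper
parameter set than apolar contacts. The published description fixes this
functional form but not the numeric constants (they are deferred to the
original scoring-function papers), so the shipped values — steric
A,B,C,D = 3.4, 3.6, 4.5, 5.5 Å, well −0.4, clash weight 20; polar-pair
2.3, 2.6, 3.1, 3.4 Å, well −2.0; plp95 with wider wells (C,D = 5.0,
6.0 and 3.4, 3.7) — are this package's own parameterization, overridable
per scenario. `chemplp` shares the pair parameters with `plp` and adds
the hydrogen-bond term, so the identity `chemplp − plp = hbond` holds
exactly and is asserted in the tests.

The hydrogen-bond term is a separable product of two linear "block"
ramps — on the H···acceptor distance deviation from 1.9 Å (tolerance
0.45 Å) and on the donor–H···acceptor angle deviation from 180°
(tolerance 60°) — times a weight of −3.0. The ligand-internal clash term
applies the repulsive branch only, over heavy-atom pairs at least four
bonds apart (pairs closer in the graph are constrained by covalent
geometry, not by the pose). The torsional term $k(1+\cos(n\varphi -
\varphi_0))$ is evaluated on the pose's torsion dof values — offsets
from the reference conformation — rather than re-measured dihedrals;
this is deterministic, consistent with the dof parameterization, and
keyed by the Tripos types of the bond atoms with an sp3–sp3 fallback
(k = 0.2, n = 3, φ₀ = 0) rather than a full force-field table.

## Ligand preparation

MOL2 parsing is delegated to `bio3d::read.mol2` behind `read_mol2()`,
which first validates section headers and declared-versus-actual record
counts; writing emits coordinates and charges at four decimals for
round-trip stability. PDBQT (which carries no bond table) is parsed
directly; connectivity is then perceived geometrically — a bond wherever
the distance is at most 1.2× the sum of covalent radii (Cordero values;
two carbons bond below 1.824 Å), never between two hydrogens — and ring
bonds are the non-bridge edges of the molecular graph. Tripos-style
types follow from element, connectivity and bond orders (amide N,
carboxylate O, sulfone/sulfoxide S as special cases). Rotatable bonds
are single, acyclic, non-terminal bonds, excluding amide C–N by default
(their partial double-bond character keeps them planar); the PDBQT
BRANCH tree is recorded but never trusted — the torsion list is always
recomputed, keeping one source of truth. Input protonation and tautomer
states are preserved verbatim; no enumeration is attempted.

Torsion rotation moves the branch with fewer heavy atoms; ties move the
branch containing the higher-indexed atom. This makes `apply_pose`
deterministic for symmetric ligands.

## What the synthetic fixtures emulate — and what they do not

`make_toy_complex()` builds a closed spherical shell of apolar
pseudo-atoms (default 16 at 5 Å) with one donor N–H aimed inward and one
acceptor O: a caricature of a buried pocket in which a centered ligand
sits in every shell atom's steric well. Generation verifies that the
planted pose outscores 40 sampled poses displaced by ≥ 2 Å and retries
with the next seed otherwise. `make_fixture_library()` reproduces the
meta-tranche/tranche/collection layout at desk scale (≤ 10⁴ compounds),
optionally with every collection holding an identical compound panel, as
the large-scale replicated benchmark library does; a manifest at the
root is the single source of truth for the expected ligand set.

These fixtures exercise file formats, typing, torsions, hydrogen
bonding, ranking and determinism. They do **not** emulate real binding
sites: no desolvation, no buried-polar penalties, no induced fit, no
realistic chemotype diversity. Passing tests therefore demonstrate the
correctness of the machinery — discretization, sampling, updates,
scoring identities, orchestration — not screening power on real targets.

## Oracle comparisons and the probe-ligand design

The engine is validated against `brute_force_dock()`, which scores every
cell midpoint of a coarse grid. Two choices make this comparison exact
rather than statistical noise. First, ants sample cell midpoints
(`sample_within = "midpoint"`), so the exhaustive minimum is a true
lower bound on anything the colony can find. Second, the toy ligand is a
single heavy atom: for a spherically symmetric probe the three
orientation dofs are exact gauge freedoms, so they are collapsed to one
interval each and the optimum cell is unique in the three translations
(5 intervals per axis, 125 cells). With the full deposit windows (±2
intervals rotational, ±1 translational) reinforcement is deliberately
smeared, which caps how sharply the trail distribution can peak; on a
full 6-dof product grid the exact-cell hit probability of a 50×20-sample
run would be dominated by that smearing rather than by learning, which
is why the oracle comparison is posed on the translations of a probe,
where the update rule's concentration is actually measurable. The
engine-versus-oracle agreement and the trail-concentration sign test in
the suite measure exactly this.

## Numerical choices and degenerate inputs

* Boundary ties in `assign_interval` go to the lower interval; $x = a_i$
  to interval 1.
* The deposit window is evaluated on interval indices (the solution's
  interval versus the candidate's), so window membership inherits the
  same tie convention.
* `local_search` requires a budget of at least $n+1$ evaluations (the
  initial simplex); an exhausted budget returns the best-so-far point,
  never an error.
* Pheromone rows are strictly positive after clamping, so selection is
  always well defined; an all-zero row (possible only by manual
  construction) raises a degenerate-distribution error.
* Per-(iteration, ant) RNG substreams are derived arithmetically from
  the task seed, so results are independent of ant evaluation order;
  per-ligand seeds are hashes of the global seed and the ligand id, so
  screens are independent of traversal order and worker count. Wall
  times are reported in a separate `timings.csv` so `ranking.csv` is
  byte-identical across reruns and worker counts.
* Scores are plain doubles; the breakdown identity
  `total = steric + hbond + clash + torsion` is exact to 1e-9 and
  asserted.

## Desk-scale problem sizes

The shipped tests and the acceptance script run at sizes chosen for a
single CPU: toy pockets of 16 shell atoms, ligands of 1–6 heavy atoms,
125–216-cell oracle grids, 24-compound fixture libraries, benchmark
panels of 12 ligands with AVE_10 (AVE_100 needs at least 100 compounds;
at desk scale N = 10 measures the same top-of-ranking mean), and reduced
iteration/local-search budgets for screening tests. These are the
package's own desk-scale study conditions; the engine defaults
(100 base iterations, 20 ants, 60-evaluation refinement) are what
`resolve_defaults()` hands production runs.

## Known limitations

* The receptor is fully rigid — no side-chain flexibility and no
  receptor hydrogen-position optimization.
* No explicit water molecules, metal coordination, interaction
  fingerprints, or experimental-constraint terms.
* The scoring constants are a package-own parameterization of the
  published functional forms; absolute score magnitudes are not
  comparable to other implementations, only orderings within one
  scoring function.
* Tripos typing covers common organic chemistry (C/N/O/S/P/halogens);
  exotic valence states raise typing errors rather than guessing.
* Geometric bond perception cannot recover bond orders from PDBQT
  beyond the aromatic flags its atom types carry.
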