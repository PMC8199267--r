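# acodock

Ant-colony optimization for protein–ligand docking and virtual screening,
as a self-contained R toolkit.

## The problem and the method

Docking predicts how a small molecule binds a rigid receptor by minimizing
a scoring function f(x) over the pose vector
x = (x₁, …, xₙ): three translations of the ligand centroid inside a
spherical search region, three orientation angles, and one torsion angle
per rotatable bond. More negative scores mean stronger predicted binding.

`acodock` searches this space with an **ant colony**. Each degree of
freedom i is discretized into intervals [z_{iℓ−1}, z_{iℓ}]; a
characteristic function assigns any continuous value to its interval.
Every interval carries a pheromone trail τ_{iℓ}(t), and each of the
colony's ants picks interval ℓ for dof i with probability

    p_{iℓ}(t) = τ_{iℓ}(t) / Σ_k τ_{ik}(t),

draws a continuous value inside it, and refines the sampled pose with
Nelder–Mead simplex local search to a local minimizer s_a. The trails then
evaporate and the iteration-best refined solution deposits:

    τ_{iℓ}(t+1) = (1 − ρ) τ_{iℓ}(t) + 1_{iℓ} Δτ,

where the indicator 1_{iℓ} marks a neighborhood window around s_a's
interval (two intervals either side for rotational dofs, wrapping at
0/360°; one either side for translations) and Δτ = |f(s_a)| when
f(s_a) < 0. Trails are clamped into MAX-MIN bounds so no interval's
probability collapses to zero.

Poses are scored with **piece-wise linear potentials** over
receptor-heavy/ligand-heavy atom pairs (a clash wall below A, a linear
descent to a flat well on [B, C], a linear return to zero at D), a
ligand-internal heavy-atom clash penalty, a Tripos-style torsional
potential k(1 + cos(nφ − φ₀)) on rotatable bonds, and — under the
`chemplp` function — angle-dependent hydrogen-bond terms. Three named
parameterizations are selectable: `plp`, `plp95`, `chemplp`.

Around the engine sits a screening layer: Tripos MOL2 read/write,
on-the-fly PDBQT→MOL2 conversion (bond perception from covalent radii,
Tripos-style atom typing, rotatable-bond detection), hierarchical
meta-tranche/tranche/collection library traversal, multi-scenario docking
with consensus (mean) scoring, log/result output routing, and AVE_N
(top-N mean score) summaries. A fixtures module generates toy
receptor–ligand complexes and libraries, with brute-force grid oracles
and a desk-scale parameter-variation benchmark.

## Worked example

```r
library(acodock)

tc <- make_toy_complex(seed = 1)            # synthetic pocket + ethanol-like ligand
sc <- docking_scenario("example", "chemplp", sphere = tc$sphere,
                       search_speed = 4,
                       aco_overrides = list(iterations = 10L, ls_budget = 20L),
                       angular_step = 60, linear_step = 1)
res <- run_aco(tc$receptor, tc$ligand, sc, seed = 42)
```

This prints (via the breakdown):

```
best score: -12.3790
breakdown: steric -10.0197 hbond -2.3593 clash 0.0000 torsion 0.0000
evaluations: 4000  iterations: 10
```

The best pose scores −12.38: about −10.0 from shell atoms sitting in the
steric well, −2.4 from one near-ideal hydrogen bond, and no internal
clash or torsional strain (the ligand is rigid). `res$pose_xyz` holds the
posed coordinates; `write_mol2(set_coords(tc$ligand, res$pose_xyz))`
exports them.

For screens, write a `control.txt` (`ligand_library_format=PDBQT|MOL2`,
`docking_scenario_names=...`, `library_root=`, `output_root=`, `workers=`,
`seed=`) plus one `input-files/<scenario>/config.txt` per scenario
(`scoring_function`, `search_speed`, `bindingsite_center x y z`,
`bindingsite_radius r`, optional `aco_ants`/`aco_evap`/`aco_sigma`), then
`run_screen(parse_control_file("control.txt"))`. The ranking CSV is
sorted by consensus score and is byte-identical for any worker count.
A thin CLI wrapper lives at `inst/scripts/acodock.R`
(`convert` / `dock` / `screen` / `report`).

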