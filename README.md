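# pentagate

Quantitative structural analysis of pentameric ligand-gated ion channel
(pLGIC) gating, for structural biologists and simulators working with
proton-gated channels such as GLIC. Given five-chain coordinate models
(PDB) and/or molecular-dynamics trajectory frame sets, the package
computes the standard geometric observables of the gating cycle:

* **Pore geometry** — a total-least-squares channel axis through the M2
  Cα ring centroids; per-residue pore radius profiles r(z) (atom-center
  distances); the hydrophobic-gate radius at 9′ (I233 Cβ ring, prime
  index = residue − 224); water occupancy of the 9′–13′ gate cylinder.
* **Superposition** — Kabsch least-squares fits (proper rotations only)
  and selection-restricted RMSD between models or per trajectory frame,
  with chain pairing by azimuthal subunit order.
* **Quaternary descriptors** — ECD *spread*, the radius of gyration about
  the channel axis of Cα 20–190, `sqrt(mean(d_perp^2))`; and domain
  *twist*, the circular-mean dihedral through the centers of mass
  (subunit-ECD, ECD, TMD, subunit-TMD).
* **Electrostatic contacts** — Na⁺ coordination of the E35 proton sensor
  (inclusive 5 Å to carboxylate oxygens), E243–K248 salt-bridge series
  (4 Å heavy-atom convention), intersubunit Cα distances across the five
  principal→complementary interfaces, contact fractions, and percentile
  bootstrap medians ± CI.
* **Loop PCA** — per-subunit observations of M2–M3 loop Cα (243–250) in
  a common subunit frame, covariance eigendecomposition, projection of
  further models or frames, and Gaussian kernel-density landscapes.
* **Synthetic ground truth** — a C5 pentamer generator producing models
  and mock trajectories (breathing, twist drift, two-state Markov
  contacts, diffusing ions, pore waters) with exact per-frame ground
  truth, so the whole pipeline is testable offline.

## Worked example

```r
library(pentagate)

spec  <- synthetic_spec(seed = 1, n_frames = 50)  # GLIC-like resting system
model <- generate_pentamer(spec)
axis  <- estimate_pore_axis(model)

gate_radius(model, axis, residue = 233, atom_name = "CB")
#> [1] 2.9
as.data.frame(pore_profile(model, axis, c(230, 237)))[1:3, ]
#>   residue prime          z radius atom_name n_chains
#> 1     237    13 -1.0593220    5.2        CA        5
#> 2     236    12 -0.6355932    5.0        CA        5
#> 3     235    11 -0.2118644    4.8        CA        5

traj <- generate_trajectory(spec)
ds   <- descriptor_series(traj)
descriptor_summary(ds, seed = 1)$spread
#> median 25.15 [24.92, 25.29] (95% bootstrap CI, n = 50, B = 10000)

contact_fraction(salt_bridge_series(traj))     # E243-K248, 4 A convention
#> [1] 0.692
mean(water_occupancy_series(traj)$count)       # waters in the 9'-13' gate
#> [1] 8
contact_fraction(ion_coordination_series(traj))  # frames with Na+ at E35
#> [1] 0.408
```

Reading: the gate Cβ ring sits 2.9 Å from the axis (a closed, dewettable
constriction is ≲3.5 Å); the profile narrows from 5.2 Å at 13′ to 4.4 Å
at the 9′ Cα ring; the ECD spread medians 25.15 Å over the trajectory's
breathing; the K248–E243 contact is formed in 69% of (frame, subunit)
observations — a resting-like regime — and the gate region holds its 8
pore waters in every frame, i.e. a hydrated (conducting-compatible)
lumen under these synthetic conditions.

For configuration-driven runs over fixtures or your own files, see
`analysis_config()` / `run_analysis()`, or the thin CLI wrapper
`inst/scripts/pentagate` (`pentagate run --config analysis.yaml`,
`pentagate synth --spec spec.yaml --out dir/`).

## Scope

No cryo-EM map handling, model refinement, probe-based (HOLE/CHAP-style)
pore pathfinding, pKa prediction, periodic-boundary imaging, or flexible
alignment. Radii are atom-center distances; models must share author
numbering over the analysis ranges. See the methods vignette
(`vignettes/pentamer-gating-analysis.Rmd`) for conventions, parameter
defaults, and design rationale.
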