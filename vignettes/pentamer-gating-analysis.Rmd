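---
title: "Quantifying pLGIC gating: pore geometry, quaternary descriptors, contacts, and loop landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pLGIC gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentagate)
```

# The scientific problem

Pentameric ligand-gated ion channels (pLGICs) couple agonist binding in the
extracellular domain (ECD) to opening of a transmembrane pore lined by the
five M2 helices. In the proton-gated prokaryotic homolog GLIC, activation is
driven by low extracellular pH, and the structural correlates of gating are
subtle: a hydrophobic constriction near the M2 position 9' (residue I233,
prime index = author residue number − 224) dewets and blocks conduction in
closed states; the ECD contracts ("spread" decreases) and rotates relative
to the transmembrane domain ("untwisting"); proton-sensing acidic residues
(E35 in the β1–β2 loop, E243 in the M2–M3 loop) exchange electrostatic
partners (Na⁺ vs. T158 of the complementary loop F, and K248 respectively);
and the M2–M3 loop — the principal ECD→pore coupling element — changes
conformation.

`pentagate` implements the quantitative side of this analysis as a reusable
package: given coordinate models (PDB) and trajectory frame sets, it
computes pore radius profiles and gate radii, rigid-body (Kabsch)
superpositions and selection-restricted RMSDs, ECD spread and domain twist,
cutoff-based contact and ion-coordination statistics with bootstrap
medians, and principal-component landscapes of M2–M3 loop conformations.
Because the interesting quantities are all geometric, every stage can be
validated against a synthetic C5 pentamer generator with exact ground
truth; that generator is itself part of the package's tested surface.

# Conventions and definitions

## Coordinate models and subunit order

A `pentamer` is a five-chain atomic model in author (PDB) numbering —
numbering is never remapped, so residue identities like E35, I233 (9'),
A237 (13') and K248 carry over directly. Alternate locations are resolved
to the highest-occupancy copy (ties toward altloc "A"); waters
(HOH/WAT/SOL/TIP3) and monovalent cations (NA/SOD) are retained as labeled
heteroatoms; insertion codes are rejected (the constructs analyzed here
have none).

Intersubunit ("principal/complementary") measures need a rotational order.
`subunit_order()` sorts chains by the azimuth of their Cα centroid about
the pore axis, counterclockwise viewed from the extracellular side, so
that the complementary neighbor of subunit *i* is *i*+1 (mod 5). This is
label-free: deposited chain identifiers play no role.

## The pore axis

No standard definition of "the channel axis" exists for an experimental
model, so the package defines one explicitly: the total-least-squares line
through the per-residue ring centroids of pore-lining Cα atoms (default M2
residues 222–247), oriented so the ECD centroid (Cα 20–190) has positive
projection. The definition is parameter-free, exactly recovers the C5 axis
of a symmetric assembly, and degrades gracefully (on a fixture with 0.1 Å
coordinate noise the angular error is below 1°; see the test suite).

## Pore radii and hydration

`pore_profile()` reports, per residue, the mean perpendicular distance of
the (up to five) symmetric copies of a named atom to the axis. Radii are
center distances — no van-der-Waals subtraction — because the displayed
quantity of interest is the Cα (or, at the gate, Cβ) ring radius; if a
probe-accessible radius is needed, subtract the relevant atomic radius
downstream. `gate_radius()` is the same quantity for a single ring and
defaults to residue 233, atom CB (the 9' constriction).

`water_occupancy()` counts water oxygens inside a closed axial slab
bounded by the Cα ring centroids of two residues (default 233 → 237, the
9'–13' gate region) and within a radial cutoff of the axis. The axial
bounds are physically determined; the radial cutoff is not, and defaults
to 6 Å — wide enough to enclose the wetted lumen at the gate, narrow
enough to exclude lipid-facing waters. It is a configurable parameter, not
a constant.

## Superposition and RMSD

`kabsch_fit()` is the closed-form least-squares rigid superposition with
proper rotations enforced (reflections excluded by the sign-corrected
SVD); all atoms carry unit weight, which is exact for the Cα-only
selections used throughout (mass differences among Cα atoms are nil).
`rmsd_between_models()` fits on one selection and measures on another,
pairing chains by azimuthal order with the cyclic offset chosen to
minimize the fitted RMSD — deposited chain labels between two models need
not correspond, and whether a published number was computed per chain or
over the whole pentamer is absorbed by this minimizing convention.

The "non-loop Cα" selection used for model comparisons is the union of
the ECD (17–192) and TMD (196–314) alignment ranges minus flexible-loop
intervals, by default β1–β2 (30–36), loop F (151–160) and M2–M3
(243–250). Published usage does not enumerate the exclusions beyond
naming these loops as flexible, so the intervals are documented
configuration (`nonloop_ca_selection()`), not hard-coded truth.

## Quaternary descriptors

*ECD spread* is the radius of gyration about the channel axis of Cα atoms
of residues 20–190 with unit weights: `sqrt(mean(d_perp^2))`. It scales
exactly with uniform radial scaling and ignores axial motion.

*Domain twist* is, per subunit, the dihedral angle through four centers of
mass — (subunit ECD, full ECD, full TMD, subunit TMD) — combined over the
five subunits by a circular mean (plain averaging would wrap at ±180°).
COMs are unit-weight Cα centroids, consistent with every other Cα-based
quantity; mass weighting is available as a documented alternative but not
the default. The residue ranges entering twist are not independently
specified anywhere, so the package reuses the spread range (20–190) for
the ECD and the trajectory-RMSD range (197–313) for the TMD. The sign
convention is fixed by construction: rotating the ECD by +10° about the
axis (counterclockwise from the extracellular side) relative to the TMD
yields +10°, and a mirror-image assembly yields −10°.

Both descriptors are recomputed against a per-frame axis estimate, so they
track the instantaneous assembly rather than a frozen frame-0 geometry.

## Contacts, coordination, and summaries

All distances are plain Euclidean; protein-internal measures are safe
without periodic imaging for whole-molecule trajectories, and the ion
search assumes ions have been imaged near the protein upstream.

* Na⁺ coordination of the proton sensor: distinct cations within an
  inclusive 5 Å of any side-chain carboxylate oxygen of any E35 copy,
  sampled every 10 ns, reported per subunit and pooled.
* The E243–K248 contact uses the standard salt-bridge convention — any
  K248 side-chain nitrogen to any E243 carboxylate oxygen within 4 Å
  (configurable); no angular hydrogen-bond criteria are applied because
  only heavy-atom geometry is available at the resolutions of interest.
* `contact_fraction()` pools (frame, subunit) cells, matching the
  "over all simulations" style of aggregation while keeping per-subunit
  series available.
* `bootstrap_median_ci()` is a percentile bootstrap of the median
  (default 95%, 10⁴ resamples, mandatory seed; the caller's RNG state is
  preserved). The confidence level is a parameter because published
  displays use different levels for different panels (95% for contact
  histograms, narrower bands elsewhere).

Trajectory observables are computed over the trailing analysis window
(default 300 ns) so that initial relaxation is excluded; window and
stride are configuration, not constants.

## Loop PCA

PCA of the M2–M3 loop treats each subunit of each model as one
observation: Cα coordinates of residues 243–250 (24 columns). The
critical, under-specified step is the frame in which observations are
compared. A naive global superposition would leave the five subunits 72°
apart and PC1 would simply measure rigid rotation. The package therefore
superposes each subunit's *flanking core* (M2 222–242 plus M3 251–270 Cα)
onto a designated reference subunit before extracting loop coordinates.
This per-subunit common frame is the package's main modeling choice in
this module and the dominant sensitivity when comparing explained-variance
fractions with published values (which is why the acceptance check on the
deposited models carries a ±4-percentage-point band around 36%/26%).

Covariance is computed over mean-centered rows with 1/(n−1) normalization
and no per-column scaling (all columns share Å units). Component signs are
fixed so each component's largest-magnitude loading is positive, making
results deterministic across eigen-solvers. Projections are plain dot
products against the training mean and components, so the training mean
maps to the origin. Landscapes use a Gaussian product-kernel density with
Scott's-rule bandwidths (`sd * n^(-1/6)` per dimension) on a 128×128 grid
spanning the data ± 3 bandwidths.

# The synthetic generator: what it emulates, and what it does not

`synthetic_spec()` + `generate_pentamer()`/`generate_trajectory()` build
an exactly C5-symmetric Cα-plus-marker skeleton about the z axis: chains
A–E at azimuths 0°, 72°, …; residues 15–314 per chain; a pore funnel whose
default ring radii narrow to a 2.9 Å Cβ gate ring at residue 233; ECD
spread 25 Å; domain twist +12°. Marker residues (E35, T158, I233, A237,
E243, K248) carry the side-chain stand-in atoms the analyses touch —
carboxylate oxygens, OG1, CB, NZ. Trajectories (default 100 frames at
10 ns, mimicking a 1 μs replicate) superimpose:

* sinusoidal ECD breathing (spread amplitude 0.5 Å, period 20 frames),
* optional linear twist drift,
* an independent two-state Markov contact process per subunit moving the
  K248 NZ between a contact pose (≈3 Å from the E243 carboxylate) and a
  released pose (defaults k_on = 0.15, k_off = 0.05 per frame, i.e. a
  75%-formed resting-like regime),
* Na⁺ ions, the first five of which start coordinated (3 Å) to the five
  E35 carboxylates and then diffuse by a 1 Å-rms random walk — emulating
  transiently bound environmental cations rather than a rigid site,
* waters resampled each frame inside (n = 8) and far outside the gate
  cylinder, and optional Gaussian coordinate noise.

All randomness flows from the single mandatory seed; fixtures written to
disk (`write_fixture()`) are byte-identical across runs with the same
seed. The trajectory container is multi-model PDB with a PDB topology:
a fixed-layout text format that standard structural tools read directly
and that makes determinism trivially checkable; the reader also accepts
any multi-model PDB produced elsewhere.

What the generator does *not* emulate: real side-chain chemistry and
packing, force-field energetics, membrane and solvent structure,
correlated loop dynamics, or experimental noise models. Passing the
recovery tests therefore demonstrates that the *estimators* are correct
(geometry, counting, statistics, determinism) — not that the biological
conclusions drawn from real trajectories are insensitive to force fields
or sampling. Checks against deposited experimental models are kept in a
separate acceptance tier that runs whenever those files are supplied
locally.

# Numerical choices and degenerate inputs

* Kabsch requires ≥ 3 paired points; near-collinear point sets produce a
  conditioning warning but still return the least-squares optimum.
* Axis estimation requires ≥ 2 residue rings; chains whose centroid falls
  on the axis, or two chains at indistinguishable azimuth, raise ordering
  errors rather than returning arbitrary orders.
* Profile residues missing their atom in more than one chain are excluded
  with a warning; symmetric selections drop incomplete positions from all
  five chains so per-chain counts stay equal.
* Water counting uses closed intervals (a water exactly on a bounding
  plane counts) and sorts inverted bounds; contact cutoffs are inclusive,
  with a 1e-9 Å² guard against floating-point ties.
* Dihedrals are undefined for collinear COM quadruples and error out
  explicitly; circular means avoid the ±180° wrap.
* Bootstrap intervals use type-7 quantiles; a single sample yields a
  degenerate (x, x) interval by construction.

# Problem sizes used by the tests

The test suite and the acceptance script size their simulations for exact
or 3-standard-error discrimination: static recovery and invariance checks
use single models (≈1,600 atoms); trajectory recovery uses 10–50 frames;
the Markov stationary-probability recovery uses 10⁴ frames × 5 subunits
(3 SE ≈ 0.019 around 0.35); bootstrap coverage uses 150 replications of
n = 25 at 10³ resamples. These sizes were chosen so each check's
discriminating power is set by its analytic error bound.

# Known limitations

* No spherical-probe pathfinding (HOLE/CHAP-style) — radii are atom-center
  distances by design; no hydrophobicity profiling.
* No flexible or sequence-based alignment: models must share author
  numbering over the analysis ranges.
* No periodic-boundary imaging; trajectories must be whole-molecule.
* No protonation-state prediction: "protonated" conditions enter only as
  alternative input topologies.
* mmCIF input is not supported; fixed-column PDB only.
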