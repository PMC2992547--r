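---
title: "Conformer sampling by epsilon-dominance multi-objective evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer sampling by epsilon-dominance multi-objective evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confevo)
```

## The problem and the model

Bioactive conformations of flexible drug-like molecules are usually not the
global minimum of any force field; they are one of many geometries of nearly
equal energy, selected by the binding site.  A conformer generator that only
minimizes energy therefore concentrates its ensemble around a handful of
minima and misses the geometry a receptor would select.  `confevo` treats
conformer generation as a *multi-objective* search in torsion space and
returns the epsilon-Pareto archive of that search as the ensemble.

The degrees of freedom are the dihedral angles of the rotatable bonds: acyclic
single-order bonds, excluding bonds to terminal atoms, amide C&ndash;N bonds,
and any bond whose rotation moves only hydrogens.  Bond lengths and bond
angles are held fixed at their input values, so a genotype is a vector of
torsions in degrees and the phenotype is the Cartesian geometry obtained by
rigid rotation about each bond axis.  Ring conformations are consequently
*not* sampled: rings keep their input pucker, and macrocyclic flexibility is
out of reach of this representation.

Two objective sets define the two sampling modes:

* **FFBM** (force-field based mode): minimize van der Waals energy and
  torsion-strain energy.  These are the only force-field terms the torsion
  representation can change (bond and angle terms are constant by
  construction), and electrostatics is excluded throughout.
* **MECBM** (multiple empirical criteria based mode): the two FFBM objectives
  plus two geometric diversity objectives, both *maximized* &mdash;
  geometric dissimilarity (GD), the heavy-atom RMSD of a conformer to the
  input conformation after rigid superposition, and the radius of gyration
  (GR), the root-mean-square heavy-atom distance from the centroid.

Maximizing GD and GR is a deliberate reconstruction choice: minimizing them
would collapse the search onto the input geometry, whereas maximization
produces the documented bias toward geometrically extensive, diverse
ensembles.  The trade-off between "fold away from the input" (GD) and "stay
extended" (GR), balanced against energy, is what spreads the Pareto front.

## The epsilon-dominance archive

Objective space (in canonical minimization form; maximized objectives are
sign-flipped) is discretized into boxes of width epsilon per objective.  The
archive keeps at most one representative per occupied box and accepts a
candidate by box-level Pareto dominance: it is rejected if any member's box
dominates its box; otherwise it evicts every member whose box it dominates;
if a member occupies the same box, the Pareto-dominating individual wins,
and an incomparable pair is decided by epsilon-normalized distance to the
box's lower corner (the incumbent keeps ties).  This gives simultaneous
convergence pressure and a guaranteed spread: two archive members always
differ by at least one epsilon box.

Default epsilons are 5.0 kcal/mol (van der Waals), 3.0 kcal/mol (torsion
strain), 0.4 &Aring; (GD) and 0.1 &Aring; (GR).

The evolutionary loop is steady-state: population and generation counts both
default to 200, giving exactly 200 initial evaluations plus 200 &times; 200
offspring evaluations.  Each iteration breeds one child from a
binary-tournament population parent and a uniformly random archive co-parent,
using blend crossover on angles along the shortest angular path (rate 0.9)
and per-gene mutation to a uniform angle (rate 1/n).  An offspring enters
the population if it is not dominated by any member, replacing a random
dominated member if one exists, otherwise a random member.  The generational
scheme is a reconstruction (the published description fixes only the two
counts at 200); it follows the canonical steady-state epsilon-MOEA design.
Initialization is uniform random torsion vectors with the input
conformation's own torsions injected as one seed individual, so the GD
reference point is always represented.

Two implementations of this loop ship in the package: a readable pure-R
reference (`run_emoea()`, which takes any evaluator function) and a compiled
twin used by `generate_ensemble()`.  Both consume R's RNG stream in exactly
the same order, and the test suite asserts they produce bitwise-identical
archives; the archive rules themselves are additionally validated against a
brute-force epsilon-Pareto filter over random candidate streams.

## Energy model

Two interchangeable backends sit behind one contract
(`energy_model("mmff94")`, `energy_model("tripos")`).  Both are documented
*approximations* of the named force-field families, not reproductions of the
published parameter tables:

* `"mmff94"`: buffered 14-7 van der Waals with element-based radii and well
  depths, full-strength 1-4 interactions, a 3-term cosine torsion potential,
  and harmonic bond/angle terms whose reference values are taken from the
  molecule's input geometry.
* `"tripos"`: Lennard-Jones 12-6, 1-4 interactions scaled by 0.5, and its own
  torsion/bond/angle constants.

Restraining bonds and angles to the input geometry is the consistent choice
for this sampler: sampling holds them fixed by construction, and minimization
then relaxes Cartesian coordinates against the same reference.  Charge-charge
terms are excluded everywhere.  The van der Waals sum is capped at 10^6
kcal/mol so that clashed geometries compare cleanly inside the MOEA instead
of producing NaN/Inf.  The published observation that ensemble quality is
insensitive to force-field choice is the design justification for accepting
approximate parameterizations here; the directional mode comparison, which is
this package's point, is reproduced under both backends.

During sampling, the "filter energy" of a conformer is vdW + torsion &mdash;
the two terms the objectives actually compute.  Any structure whose filter
energy exceeds the running minimum by more than the 20 kcal/mol window is
discarded as soon as it is identified: it is neither archived nor inserted
into the population, though it still counts against the evaluation budget.
This in-run discard matters.  If the window were applied only retrospectively,
the archive would fill with clashed but maximally-extended geometries (high
GD/GR, enormous vdW) and the final window would collapse a multi-criteria
ensemble to a single conformer &mdash; inverting the characteristic ordering
in which the multi-criteria ensembles are several times larger than the
force-field-only ones.  The retrospective re-filter against the final minimum
is applied as well, followed by greedy deduplication (heavy-atom,
symmetry-aware best-fit RMSD below 0.2 &Aring; counts as a duplicate; the
threshold sits well below the 0.5 &Aring; resolution of any downstream
analysis) and truncation to the 600 lowest-energy conformers.

Optional post-refinement minimizes every surviving conformer under the full
force field excluding electrostatics with Polak-Ribi&egrave;re conjugate
gradients (Armijo backtracking line search, gradients by central finite
differences), stopping at a 0.01 kcal&middot;mol^-1^&middot;&Aring;^-1^
gradient max-norm or 100 steps.  The refinement backend may differ from the
sampling backend (the mixed-force-field strategy); after refinement the
window and deduplication are re-applied on the minimized total energy.

## Geometry conventions

All RMSD, GD and GR computations use heavy atoms only, with unit weights:
hydrogens are placement artifacts of whichever force field or builder
produced them, and mass-weighting is not used anywhere.  Superposition is a
Kabsch least-squares fit (validated in the tests against an independent
quaternion implementation).  Best-fit RMSD additionally minimizes over the
element-colored automorphisms of the heavy-atom graph, enumerated from bliss
generators with a cap of 10,000; beyond the cap the identity mapping is used
with a warning.  Dihedrals are signed, in degrees, wrapped to [-180, 180);
collinear quads raise an undefined-dihedral error.

## What the synthetic generator emulates

`make_fixture()` builds chain, branched and ring-containing molecules of C,
N and O with explicit hydrogens on idealized sp3 internal coordinates
(tetrahedral angles, standard bond lengths, rings as ideal chairs).  The
input conformation is the *extended* all-anti chain &mdash; deliberately so,
because that is what standard 2D-to-3D embedders emit as their single
low-energy guess, and because an extended input is what makes GD and GR
genuinely antagonistic.  Planted targets (`plant_target()`) drive the
rotatable torsions to seeded random values and serve as synthetic "bioactive"
references.

What a green synthetic test does **not** establish: fixtures share their bond
lengths and angles with the target by construction, which flatters recovery
relative to crystallographic references; they contain no charged or aromatic
ring systems, no amide-rich chains, no macrocycles; and absolute recovery
percentages on synthetic fixtures are not comparable to rates measured on
PDB-derived sets.  The benchmark harness (`run_benchmark()`,
`synthetic_recovery_benchmark()`) therefore asserts *directional* statements
only: under identical seeds and budgets the multi-criteria mode recovers at
least as many planted targets within 1 &Aring; and produces larger unique
ensembles than the force-field-only mode.

## Numerical choices and degenerate inputs

* Torsion driving preserves bond lengths/angles to 1e-6 &Aring; / 1e-4
  degrees (property-tested); the set/measure round trip closes to 1e-4
  degrees.
* Heat-map bins are equal-width and half-open [lo, hi) with the final bin
  closed, on a per-molecule scale shared across protocols and restricted to
  conformers within the 20 kcal/mol window; a degenerate all-equal scale
  collapses to a single occupied bin.  The default of 20 bins is a display
  choice.
* A molecule with no rotatable bonds returns its input conformation as a
  singleton ensemble.  Empty conformer lists pass through the window filter
  unchanged; an empty molecule list is an I/O error.
* Archive tie-breaks use epsilon-normalized corner distance so that
  objectives with different units compare on a common scale; the incumbent
  wins exact ties, making acceptance deterministic.
* Every run is reproducible from its seed; the CLI logs configuration, seed
  and package version.

## Known limitations

Ring and macrocycle conformations are not sampled.  Stereocenters are never
inverted.  Protonation states are taken as given.  The energy backends are
element-typed approximations &mdash; adequate for ranking torsional
conformers of organic molecules, not for quantitative energetics; molecules
containing elements outside C, O, N, S, F, Cl, Br, P, H fail typing with an
explicit error and should be filtered out first
(`filter_allowed_elements()`).  Absolute bioactive-conformation recovery
rates depend on input-geometry provenance and force-field fidelity and are
expected to differ from any published figures; the mode ordering and
ensemble-size ratio are the robust, tested claims.
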