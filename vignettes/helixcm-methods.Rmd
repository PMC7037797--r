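---
title: "Sampling and measuring transmembrane helix conformations with helixcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling and measuring transmembrane helix conformations with helixcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixcm)
```

## The problem

Class A G-protein-coupled receptors thread the membrane with seven
transmembrane helices (TMHs).  Helix-bending residues — serine/threonine with
particular chi1 rotamers, glycine, and above all proline — let individual
TMHs kink, and the kinks reshape the ligand-binding crevice and the packing
of the whole bundle.  When a receptor of unknown structure is modelled on a
template that lacks one of its bending residues, the modeller must ask: what
shapes can this helix actually adopt, and which of them fit the bundle?

`helixcm` implements the computational machinery for that question as a
reusable toolkit:

* a two-phase Monte-Carlo/simulated-annealing conformational sampler over
  hinge-region backbone dihedrals ("Conformational Memories"),
* helix-axis fitting and kink geometry (bend, wobble, face shift),
* Ballesteros–Weinstein (BW) residue numbering,
* classification of the inactive-state microswitches GPCR modellers audit
  (chi1 rotamers, the ionic lock, toggle-switch triads, the sodium pocket,
  inter-helical hydrogen-bond networks, aromatic stacking classes),
* systematic torsion scans of small molecules with conformational-cost
  accounting, and
* per-residue decomposition of ligand–receptor Coulombic and van der Waals
  interaction energies.

Everything is testable offline: the `synthetic_data` generators build ideal
and kinked helices, rotamer probes and toy ligand–pocket complexes with
machine-readable ground truth.

## Structures and internal coordinates

A structure (`helix`) is a tibble of heavy-atom records.  Internal
coordinates — phi, psi, omega, the N–CA–C bond angle ("tau") and side-chain
chi torsions — are measured with `internal_coords()` and structures are
rebuilt by sequential NeRF-style extension with `cartesian_from_internal()`.
Bond lengths and the remaining bond angles come from a single embedded
ideal-geometry table (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å); the sampler
varies only dihedrals and the N–CA–C angle, so fixed covalent geometry is
the natural representation.  For structures built from internal coordinates
the round trip internal → Cartesian → internal is the identity to well below
1e-6 Å.

```{r internal}
h <- build_ideal_helix(strrep("A", 18))
head(internal_coords(h), 3)
```

Side chains are placed from per-residue Z-matrix templates covering all
twenty amino acids, with chi1 adjustable (default trans).  Proline's ring is
treated flexibly: CG/CD follow the side-chain frame, and the ring-closure
bond is used only for bonded-pair exclusions, so sampling phi of a proline
slightly distorts the ring geometry.  This is a deliberate simplification —
the sampler constrains proline phi to (−120°, 40°) anyway, where the
distortion is small.

## The Conformational Memories sampler

The sampler explores the "hinge region": a helix-bending residue plus the
four residues preceding it (five residues).  At every Monte-Carlo step two
distinct free dihedrals are redrawn uniformly within their allowed ranges
and one free bond angle is perturbed within ±8° of its ideal value; the
candidate is accepted by the Metropolis criterion with
k~B~ = 0.0019872 kcal/(mol·K).  Dihedral ranges default to the full circle,
except for prolines, which get the database-derived windows
−120° < phi < 40°, −70° < psi < 0°, and have omega freed over
(−160°, 160°); for non-proline residues omega stays fixed, since peptide
bonds are rigidly planar unless a proline is involved.

The two phases:

1. **Exploratory.**  Anneal from 3000 K to 310 K in 18 temperature steps
   (geometric ladder — the method's sources state only the endpoints and the
   step count, and a geometric ladder is standard simulated-annealing
   practice), 50,000 MC steps per temperature.  Every accepted state
   deposits the current value of every free dihedral into a 10°-bin
   histogram: the "memories".
2. **Biased.**  Re-anneal from 749.4 K to 310 K in nine steps, proposing
   only within the *retained* bins — bins holding at least 1% of a
   dihedral's accepted samples.  Both the bin width and the retention
   threshold are arguments of `run_cm()`, since "highly populated" is a
   judgement call.

The output ensemble (112 conformers by default, mirroring the ensembles the
method is known for) is taken at evenly spaced accepted states of the final
310 K temperature of the biased phase, with no post-minimisation.  The inner
loop is compiled code: a dihedral move rotates the distal atom block rigidly
about the bond axis, which preserves every other internal coordinate
exactly, and a bond-angle move is followed by restoring the two adjacent
torsion readings so it, too, is a pure internal-coordinate change.  The
kernel uses its own splitmix64 random stream, so a run is bit-reproducible
from its seed on any platform.

```{r cm, eval = FALSE}
h <- build_ideal_helix(strrep("A", 26))
sp <- hinge_spec(h, 17)          # residues 13-17 form the hinge region
run <- run_cm(h, sp, seed = 42)  # ~3-4 min on one CPU at full scale
glance(run)
sup <- superpose_ensemble(run, anchor = 1:12)
```

A full-scale run (50,000 steps × 27 temperatures on a 5-residue hinge of a
26-residue polyalanine helix, ~130 atoms) takes a few minutes on one CPU.
The examples in this vignette and most tests use shorter ladders
(6 + 4 temperatures, 2,000 steps each), which exercise the identical code
path; the full-scale configuration is run once in the test suite and in the
acceptance script.

### The energy backend

The sampler needs relative energies, not absolute ones, and every
quantitative claim in the package is checked against closed forms or
independent oracles.  The backend is therefore a minimal documented force
field rather than a re-implementation of a published one: per-atom partial
charges with wildcard fallbacks, one Lennard-Jones class per element
(12-6 form, `eps(r_min) = -eps` at the like-pair minimum, arithmetic-mean
radii and geometric-mean depths for unlike pairs), short cosine torsion
series, and a configurable dielectric.  The defaults live in a YAML
parameter file shipped with the package (`forcefield_default.yaml`) with
sections `charges`, `lj`, `torsions` and `dielectric`.

Numerical conventions worth knowing:

* Coulomb energy is `332.0636 q_i q_j / (eps(r) · r)` kcal/mol with the
  distance-dependent model `eps(r) = c·r`, so the distance enters squared.
  Sampling defaults to `c = 1`; interaction decomposition uses `c = 2`.
* 1-2 and 1-3 bonded pairs are excluded; 1-4 pairs enter at full weight by
  default (`scale14` exposes a multiplier).
* Nonbonded and electrostatic cutoffs default to 8 Å and 20 Å; pairs beyond
  a cutoff contribute zero to that term.  The 4 Å "hydrogen-bonding"
  distance is honoured as a reporting criterion (close polar pairs are
  flagged in interaction tables), not as a separate energy term — the
  simplified force field has no explicit hydrogen-bond potential.
* There is no CMAP-style backbone cross-term and no bond/angle stretch
  energy; the sampled bond angle is geometric only.

### What the sampling tests show

At fixed temperature on a flat landscape the accepted-value histogram of a
free dihedral is uniform; under a single analytic 3-fold torsion potential
the *chain* marginal (the state recorded every step, holds included)
matches the quadrature-normalised Boltzmann density to a Kolmogorov–Smirnov
distance well under 0.05 at 5×10⁴ samples.  The chain marginal is the right
object to test: with an independence proposal the distribution of *newly
accepted* values is provably not Boltzmann, only the chain is.

## Kink geometry: bend, wobble, face shift

`fit_helix_axis()` takes local helix centers as means of four consecutive CA
positions, which cancels most of the ~100°/residue periodicity, smooths the
centers once more with a three-point mean (the four-residue window alone
leaves a residual first harmonic of ~0.25 Å; the second pass brings the
axis residual of an ideal helix below 0.1 Å), and fits the least-squares
line, oriented N→C.

`compute_kink()` reports, about a hinge residue:

* **bend** — the angle between the axes fitted to the pre-hinge
  (residues ≤ hinge) and post-hinge (residues > hinge) segments;
* **wobble** — the azimuth of the distal axis about the proximal axis,
  measured right-handedly about the proximal N→C direction from the
  hinge-CA reference direction (the hinge CA's offset from the proximal
  axis).  Wobble is intrinsically ill-conditioned as the bend vanishes; it
  is always reported but flagged `wobble_reliable = FALSE` below a 10° bend;
* **face shift** — the mean change in helical phase of the post-hinge
  residues relative to the phase extrapolated from the pre-hinge segment,
  with the phase reference transported across the kink by the minimal
  rotation between the two axes.

Two design choices are the package's own.  First, the extrapolation slope
defaults to the pre-hinge segment's *measured* phase per residue rather
than a fixed 100°/residue: a fixed slope accumulates systematic drift of
several degrees over ten residues whenever the actual periodicity differs
by even half a degree, while the self-consistent slope cancels it
(`phase_per_residue = 100` restores the fixed convention).  Second, the
wobble sign convention (right-handed about N→C) is documented rather than
asserted to match any published table, because the reference frame used in
published kink tables is not recoverable from their text.  The ground truth
for all three descriptors is the synthetic construction: `build_kinked_helix()`
applies known rigid transforms and records them, and the recovery bounds
(bend within 1°, face shift within 2°, wobble within 5° for bends ≥ 10°,
across bends of 5–40° and face shifts of 0, ±30°, ±90°) are enforced in the
test suite.

```{r kink}
k <- build_kinked_helix(strrep("A", 25), hinge = 13, bend = 20, wobble = 60,
                        face_shift = 30)
compute_kink(k$helix, 13)
format_kink_table(tibble::tibble(helix = "TMH1", hinge = "T13",
                                 kink = list(compute_kink(k$helix, 13))))
```

## Ballesteros–Weinstein numbering and microswitches

`assign_bw_numbers()` anchors each helix at its most conserved residue
(label x.50) and numbers outward, so the residue before the TMH1 anchor of
a receptor with an acidic residue there is E1.49 and the one after is
A1.51.  Residues outside every helix range keep their absolute sequence
number, rendered like `R(220)`.  The map is invertible and serialises as a
two-column TSV.

The microswitch layer classifies the indicators GPCR modellers audit in an
inactive-state model:

* **chi1 rotamers** — g+ ≈ −60° (window [−120°, 0°)), g− ≈ +60°
  ([0°, 120°)), trans otherwise.  The windows partition the circle and are
  configurable; the centres follow the usage standard in the GPCR-modelling
  literature.
* **ionic lock** — the 3.50–6.30 interaction at the intracellular helix
  ends; in receptors where 6.30 is a threonine this is an arginine–threonine
  hydrogen bond rather than a salt bridge, so the detector is written as a
  donor/acceptor distance-and-angle test: formed when the minimum polar
  side-chain heavy-atom distance is ≤ 3.5 Å and the antecedent–donor–
  acceptor angle is ≥ 120° (inclusive bounds; both thresholds are the
  common structural-biology defaults and are configurable).
* **aromatic stacking** — ring pairs within 7 Å of centroid distance are
  `parallel` (interplanar angle ≤ 30°), `tilted-T` (30–60°), or
  near-perpendicular (60–90°), the latter split into `T-stack` when the
  centroid–centroid vector lies within 40° of either ring normal and
  `edge-to-face` otherwise — the spec of the near-perpendicular split is
  this package's own documented convention.
* **contact audits** — expected hydrogen-bond networks (e.g. the TMH1-2-7
  N1.50–D2.50–N7.49 network) and aromatic pairs are checked one by one;
  labels absent from the map come back `unresolvable` rather than erroring.
* **sodium pocket** — presence of the polar set N1.50, D2.50, S3.39, N7.49,
  Y7.53.

The toggle-switch triad defaults to 3.36/6.48/5.47 but is an argument:
whether the 5.47 rotamer belongs to the operational toggle definition or is
commentary varies between descriptions, so membership is configuration, not
code.

## Interaction-energy decomposition

`pairwise_interaction()` decomposes a bound ligand's nonbonded interaction
into per-residue Coulomb and van der Waals terms: only residues with at
least one atom within a 5 Å shell of the ligand are tabulated; terms use
the 8 Å / 20 Å cutoffs and a distance-dependent dielectric of 2
(`eps(r) = 2r`, the standard reading of a "distance-dependent dielectric of
2"); rows are sorted most stabilising first, and the per-residue sums equal
the direct total over the same atom pairs to 1e-8 kcal/mol by construction
and by test.  Ligand–receptor polar pairs within 4 Å are flagged as
potential hydrogen bonds in an attribute.  Published per-complex totals
from commercial force fields are not comparable quantities for this
backend and are not targets; the oracle is the closed-form direct sum on
toy complexes.

```{r interaction}
tc <- build_toy_complex(4, charge_pattern = c(-1, 0.5), seed = 2)
pairwise_interaction(tc$complex, "LIG", tc$params)
```

## Torsion scans and conformational cost

`enumerate_and_minimize()` seeds the Cartesian product of fold rotamers
(120° increments for 3-fold bonds, 180° for 2-fold) and locally minimises
each start on the torsional coordinates.  Each minimisation is box-bounded
to half the well spacing around its start: on periodic surfaces an
unconstrained quasi-Newton line search can hop wells, which would make the
retained set depend on the seeding order.  Duplicates closer than 20° on
every torsion are merged (coarser than minimisation noise, finer than the
120° grid).  `conformational_cost()` is the single-point energy of a docked
pose minus the energy of the global-minimum conformer after relaxation to a
gradient below 0.01 kcal/mol/deg — by construction non-negative when the
global minimum is genuine.  Costs computed with this backend are
method-consistent quantities; they are not comparable with costs from
quantum-chemical or commercial force fields.

## The synthetic-data generators

`build_ideal_helix()` (phi = −63°, psi = −42°, omega = 180°, tau = 111°
defaults — the values that give 1.5 Å rise and 3.6 residues/turn),
`build_kinked_helix()` (known rigid transforms, optional isotropic Gaussian
coordinate noise) and `build_toy_complex()` (recorded distances, charges
and a matching force field, with the expected interaction table computed by
an independent scalar double loop) are first-class, seed-deterministic
functions.  In the kink generator the rotation axis is placed at azimuth
wobble + 90° so that the recovered distal-axis azimuth equals the recorded
truth exactly; the truth record holds exactly the applied transforms.

What passing these tests does and does not show: the generators produce
ideal covalent geometry, isolated helices, isotropic noise and single-atom
"residues".  Recovery under those conditions validates the estimators'
correctness — axis fitting, phase bookkeeping, energy bookkeeping — but
says nothing about force-field realism, membrane context, or how well a
five-residue hinge model captures a real TMH's flexibility.

## Numerical choices and limitations

* Angles are degrees everywhere; dihedrals wrap to (−180°, 180°];
  temperatures are Kelvin; energies kcal/mol; lengths Å.
* Superposition is Kabsch (SVD, proper rotations only); at least three
  atoms are required, and anchor segments of fewer than three residues are
  rejected as under-determined.
* PDB parsing is delegated to bio3d with a pre-scan that reports malformed
  ATOM records by line number; the first alternate location and, on
  request, a single model are kept deterministically.  Writing is
  fixed-width at the PDB's three-decimal precision, with MODEL/ENDMDL for
  ensembles.
* If every bin of a free dihedral falls below the retention threshold the
  biased phase refuses to run and says so; if the final temperature accepts
  no states the error carries the full acceptance-rate trace.
* Degenerate (near-collinear) CA traces are fitted but flagged, with a
  warning.
* The package does not build homology models, place hydrogens, run
  molecular dynamics, dock ligands, or reproduce any published model's
  coordinates or energies; it provides the measurement and sampling
  machinery those workflows need.
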