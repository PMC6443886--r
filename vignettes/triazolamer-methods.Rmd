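---
title: "Restrained conformational analysis of peptidotriazolamers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained conformational analysis of peptidotriazolamers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triazolamer)
```

## The problem this package addresses

Peptidotriazolamers are hybrid foldamers in which every second amide bond of
a peptide is replaced by a 1,4-disubstituted 1H-1,2,3-triazole ring, with
side chains conserved. The triazole is a trans-amide isostere: it preserves
the donor/acceptor pattern approximately while changing backbone spacing and
rigidity, which makes the conformational behaviour of these oligomers — do
they fold compactly, and does stereochemistry control the fold? — the central
experimental question.

The standard structure-determination workflow for such small foldamers is
NMR-driven: ROESY cross-peak volumes are converted into interproton distance
bounds, a restrained conformational search (classically, many parallel
simulated-annealing runs in the gas phase) produces candidate structures,
restraints that no candidate can satisfy are treated as spectral
interpretation artifacts and pruned, and the refined ensemble is analysed by
backbone-RMSD clustering. This package implements that entire workflow at
desk scale, together with the analysis suite used to characterise resulting
trajectories (superposed RMSD and radius-of-gyration series, Ramachandran-
style torsion distributions, hierarchical clustering with representative
selection and cluster merging, and radial distribution functions), and a
synthetic-data generator that provides every input with known ground truth.

## The molecular model

### Topology and nomenclature

`parse_sequence()` reads the field's sequence notation, e.g.
`"Boc-Ala-ValΨ[4Tz]Phe-LeuΨ[4Tz]Phe-LeuΨ[4Tz]Val-OAll"`. A `Ψ[4Tz]` token
replaces the central amide of a dipeptide by a triazole: the residue left of
the token becomes a *4n* residue (its CA bonds to ring carbon C4, the
propargylamine-derived side) and the residue right of it a *4c* residue (its
CA bonds to ring nitrogen N1, the azido-acid-derived side). Position indices
count each ring as its own position, so the heptamer above numbers Ala1,
V4n2, ring 3, F4c4, ..., V4c10 — matching the labelling used for dihedral
tables of such compounds.

The model is deliberately coarse: backbone N, CA, C(=O), O plus the ester
oxygen and small cap fragments; all five ring atoms plus the ring proton H5;
the amide and alpha protons; and side chains reduced to CB plus a single
centroid pseudo-atom whose mass is the summed heavy-atom mass of the side
chain it replaces (glycine has neither). No other protons, no protonation
states, no force-field-quality geometry. This is sufficient — and
intentionally no more than sufficient — for torsion-space conformational
analysis against interproton restraints.

### Geometry as internal coordinates

`build_conformation()` places atoms sequentially (the NeRF construction)
from a fixed ideal-geometry table (`ideal_geometry()`): standard peptide
bond lengths and angles, amide omega fixed trans at 180 degrees, and the
triazole as a rigid planar pentagon with 1.35 Angstrom bonds and 108 degree
interior angles (the pentagon closes exactly, which the tests assert). The
only degrees of freedom are the per-residue backbone torsions phi and psi,
so a conformation is fully determined by a `torsion_state()` — and
`measure_torsions()` inverts the builder exactly (round-trips agree to
better than 1e-6 degrees).

Because the ring interrupts the classical phi/psi definition, triazole-aware
quadruples are used, taking the shortest through-ring path (N1–C5–C4):

| residue kind | phi | psi |
|---|---|---|
| amide | C(prev)–N–CA–C | N–CA–C–N(next) |
| 4n | C(prev)–N–CA–C4 | N–CA–C4–C5 |
| 4c | C5–N1–CA–C | N1–CA–C–N(next) |

The C-terminal psi is measured to the ester oxygen and the first phi to the
N-cap carbonyl carbon (or the amine proton for uncapped chains). Any
consistent choice of quadruples suffices for distributions; this one is used
everywhere in the package. Dihedrals follow the IUPAC convention (cis = 0,
sign by the right-hand rule along the central bond, range (−180, 180]).
Note that the IUPAC torsion is *invariant* under full reversal of the atom
order — phi(A–B–C–D) = phi(D–C–B–A) — while mirror reflection negates it;
the chirality tests rely on the latter. Stereocenters are realised by a
fixed improper-dihedral offset for CB (mirrored for (R)-residues), and
`measure_chirality()` reads the label back from coordinates; mirroring a
structure flips every L to D while glycine is unaffected.

The backbone selection used for RMSD and clustering is, per position:
N, C(=O), CA and the three ring nitrogens N1, N2, N3. The convention of
including only the ring nitrogens (not C4/C5) follows the tighter of the two
selection statements available for this compound class; the selection is
configurable (`backbone_selection()`), and adding C4/C5 changes RMSD values
only marginally since the ring is rigid.

## Restraints

`peaks_to_distances()` applies the isolated-spin-pair calibration
r = r_ref (I_ref / I)^(1/6) against a single reference peak of known
distance. Only the intensity *ratio* enters, so global rescaling of a peak
table is a no-op (tested). No spin-diffusion or offset corrections are
attempted.

`restraint_energy()` is the AMBER-style flat-bottom upper-bound penalty
E = k max(0, r − r_upper)^2 with k = 32 kcal mol⁻¹ Å⁻² by default — note the
k·delta² convention (not ½k·delta²), matching the restraint input convention
of the simulation package this protocol historically used: a violation of
exactly 1 Angstrom costs 32 kcal/mol. Upper bounds get zero slack by
default; because NOE practice often adds 0.5–1.0 Angstrom, slack is an
explicit parameter of `distances_to_restraints()`. Methyl/methylene and
other side-chain protons map to the side-chain centroid pseudo-atom with no
multiplicity correction.

## The sampler: Metropolis Monte Carlo as a stand-in for restrained MD

The historical protocol anneals with restrained gas-phase molecular dynamics
under a bespoke triazole force field. Reimplementing that force field is out
of scope, so the sampler substitutes single-torsion Metropolis Monte Carlo
in phi/psi space against a stand-in energy:

* **steric**: capped soft-core repulsion eps (sigma_ij / r)^12 over nonbonded
  pairs more than three bonds apart, sigma_ij the arithmetic mean of per-role
  contact radii (backbone 1.5, CB 1.7, centroid 2.2, protons 1.0 Angstrom),
  eps = 1 kcal/mol, capped at 100 kcal/mol per pair and truncated beyond
  3 sigma where its value is below 5e-7. This term is declared non-physical;
  it exists solely to prevent chain self-intersection.
* **torsion**: a planarity restoring term K(1 + cos(2 omega − 180°)) on the
  amide omega dihedrals. For conformers built by the rigid builder it is
  identically zero (omega is a Z-matrix constant); it is retained so that
  externally supplied coordinates are scored sensibly.
* **restraint**: the flat-bottom penalties above.

Moves perturb one uniformly chosen torsion by Gaussian noise with
sigma_move = 30° sqrt(T / 600 K), clamped to [2°, 30°] — large moves for
barrier crossing at the 600 K plateau, fine moves while cooling. Acceptance
follows min(1, exp(−dE/RT)) with R = 1.98720425864e-3 kcal mol⁻¹ K⁻¹; stages
at T = 0 use greedy descent (accept iff dE ≤ 0), avoiding the division by
zero. All replicas start from the fully extended (all-180°) conformer, the
natural reference state given that no starting structures are published for
these compounds.

The staged temperature protocol is preserved exactly:
`default_sa_schedule()` is (10 K, 5 ps; 100 K, 5 ps; 200 K, 90 ps; 600 K,
400 ps; 400 K, 100 ps; 200 K, 200 ps; 100 K, 75 ps; 10 K, 20 ps; 0 K, 5 ps),
900 ps in total. (The protocol's prose calls this run "1 ns-long"; the
stage list, which sums to 900 ps, is taken as authoritative and
`schedule_total()` reports 900.) Picoseconds are mapped to Monte-Carlo steps
by `steps_per_ps` (default 100, i.e. 90,000 steps per replica) so stage
*proportions* are preserved; there is no physical time at desk scale. The
solvated heat-up protocol (890 ps total) is kept as
`default_heatup_schedule()` for protocol bookkeeping. A campaign
(`run_campaign()`) runs n_replicas (default 100, matching the
100-parallel-runs protocol) with sequential seeds base_seed + i − 1;
everything is bit-reproducible given the seeds.

## Restraint pruning

After a campaign, each restraint's penalty statistic across replicas is
compared with a ceiling of 5 kcal/mol; restraints above the ceiling are
deactivated (never deleted — the audit trail is preserved) and the campaign
repeats until a pass removes nothing (`refine()`). Termination is guaranteed
in at most as many iterations as there are restraints.

Two interpretation decisions deserve note:

* **Inequality direction.** The protocol's prose literally says restraints
  with penalties *below* 5 kcal/mol were removed, which contradicts both its
  own stopping rule ("until no restraint passed the penalty ceiling") and
  universal NOE practice. Restraints are removed when the statistic
  *exceeds* the ceiling.
* **Aggregation across replicas.** The protocol does not say how 100 replica
  penalties become one number per restraint. The default here is the
  per-replica *minimum*: a restraint is called an artifact only if even the
  best replica violates it, which is the most conservative reading. Mean and
  median are available for sensitivity analysis. Final-conformer penalties
  (not trajectory averages) are used.

A subtlety the test suite leans on: because NOE restraints are *upper*
bounds, a restraint set derived from any conformer is also satisfied by more
compact conformations. A "contradictory" restraint that is merely short
(say, 2 Angstrom between chain termini) is therefore *not* an artifact the
pruning rule can recover — the annealer simply folds the chain until it is
satisfied. Genuinely unsatisfiable restraints must demand distances below
the covalent-geometry minimum; `plant_artifact_restraints()` constructs
exactly those (bounds of 0.5 Angstrom on intra-residue proton pairs whose
eclipsed minimum is about 1.26 Angstrom, leaving at least ~18 kcal/mol of
irreducible penalty), and the planted-artifact recovery test uses them.

## Trajectory analysis

* **Superposition** is the SVD-based Kabsch algorithm restricted to proper
  rotations (determinant correction), so mirror images are never silently
  superposed. RMSD series use the run's starting structure as reference, not
  the trajectory mean, matching the protocol's convention.
* **Clustering** is hierarchical agglomerative clustering on the pairwise
  superposed backbone-RMSD matrix via `stats::hclust`, cut at a fixed
  10 clusters by default (the protocol's value; no elbow/silhouette selection
  is attempted because the protocol specifies the count). Average linkage is
  the default — the protocol names only "hierarchical agglomerative", and
  average linkage is the default of the tool it cites — with single/complete
  available. The representative of a cluster is its medoid. A dual-route
  test compares partitions against an independently coded average-linkage
  implementation on small instances.
* **Merging**: clusters whose representative-to-representative backbone RMSD
  falls below a threshold (default 1.0 Angstrom, chosen because reported
  merges of this kind occurred at 0.54 and 0.81 Angstrom) are merged
  iteratively, closest pair first; populations re-sum exactly and the merged
  representative is recomputed.
* **Radial distribution functions** use 0.1 Angstrom bins and normalise by
  4 pi r² dr times the bulk number density of water, 0.033456 per cubic
  Angstrom, by default (override `density` for DMSO or other solvents).
  Inputs are treated as non-periodic point sets: there is no minimum-image
  handling, which is a documented limitation — appropriate for the synthetic
  point-set inputs and for solute-internal RDFs, not for solvent boxes.
* **Torsion distributions** pool per-residue (phi, psi) into a 2-D histogram
  on (−180, 180]² with 5 degree bins by default; undefined dihedrals
  (collinear central triplets) are skipped and counted, never fatal.

## The synthetic-data generator

Because no structures or restraint lists are deposited for this compound
class, all tests run on synthetic data with known ground truth:

* **Templates** (`template_torsions()`): `extended` (all 180°), `helix`
  (amide (−60, −30); 4n (−60, −150); 4c (−100, −30), periodic over the
  alternating backbone), and `twisted_s` (two helical blocks of opposite
  handedness). These are package fixtures chosen once, at design time, for
  compact clash-free geometry under this builder; they are *not* the
  (undeposited) experimental structures, and no test treats them as such.
* **Trajectories** (`generate_trajectory()`): per frame, a mixture state is
  drawn by the population weights and its template torsions are perturbed by
  i.i.d. Gaussian noise. The default noise of 5.7 degrees was calibrated
  once to give a mean intra-state backbone RMSD of 0.3 Angstrom on the
  heptamer; the helix and extended templates sit 2.9 Angstrom apart, so the
  two-state recovery problem has a separation-to-noise ratio near 10.
* **ROESY tables** (`forward_roesy()`): intensities I_ref (r_ref/r)^6 with
  multiplicative log-normal noise (sigma_log = 0.1 by default; positivity is
  preserved by construction) for every proton/pseudo-proton pair within
  5 Angstrom, plus one noise-free calibration pair. At zero noise the
  forward model and `peaks_to_distances()` are exact inverses (tested to
  1e-12 relative).
* **Ideal-gas point sets** (`ideal_gas_frames()`): Poisson-count uniform
  points at a requested density, optionally with one planted point at a
  fixed radius — the RDF null and delta-peak inputs.

What a green test does and does not establish: the synthetic world has
rigid ideal geometry, isolated-spin-pair NOEs, no solvent, and no force
field. Green tests establish that the *protocol machinery* — calibration,
restrained search, pruning logic, clustering, normalization — is correct
and deterministic; they do not validate conformational predictions for real
molecules, which would require the external force field and solvated MD this
package deliberately does not reimplement.

## Numerical choices and degenerate inputs

* Angles live in (−180, 180]; wrapping maps −180 to +180. Histogram bins are
  right-closed to match.
* Undefined dihedrals yield NA with a warning; a zero-length central bond is
  an error.
* Kabsch requires ≥ 3 non-collinear points; collinear selections are
  rejected.
* Overlapping atoms (r < 0.01 Angstrom) contribute the steric cap and set a
  flag rather than raising.
* Infeasible restraints do not abort the annealer; replicas complete and
  report their irreducible penalty (that is what pruning consumes).
* The Monte-Carlo kernels draw from R's RNG, so `set.seed()` governs every
  stochastic path; campaigns assign replica seeds deterministically, and the
  pipeline derives all stage seeds from one master seed. Determinism is
  asserted byte-for-byte on the pipeline's outputs.
* Ties in cluster relabelling are broken by first occurrence; merging takes
  the closest representative pair first.

## The pipeline

`run_pipeline()` chains the stages — parse, derive restraints (synthetic
forward model or a peak-table file), refine under the SA campaign, select
the representative (main-cluster medoid among replica finals, mirroring the
protocol's selection of a starting structure for solvated MD), run the
constant-temperature (300 K) production Monte-Carlo stand-in (or ingest an
external multi-model PDB/XYZ trajectory), analyse, and write a manifest with
a config hash and md5 checksums. Re-running with an unchanged configuration
is a no-op unless forced. "Solvent" is a metadata tag at desk scale: it
selects analysis conventions (e.g. the RDF density) and labels outputs —
the stand-in sampler has no solvent model, and the package does not claim
otherwise. `plan_campaign()` enumerates molecule × solvent × replica run
matrices (e.g. 3 molecules × 2 solvents × 4 replicas = 24 runs) with unique
deterministic seeds.

## Known limitations

* The stand-in energy is not a force field: populations, energies and
  representative structures from the production stand-in characterise the
  machinery, not the chemistry.
* Torsion space only: bond lengths/angles never relax, and the triazole
  cannot pucker (it is aromatic-planar in reality too, so this is mild).
* Single-conformer NOE interpretation: no r⁻⁶ ensemble averaging across
  frames, no multiplicity corrections for pseudo-atoms.
* RDFs assume non-periodic inputs.
* The glycine model carries a single alpha proton placed with a fixed
  improper offset, so an all-glycine chain is mirror-symmetric only up to
  that proton; the mirror-image tests therefore superpose on the remaining
  atoms.
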