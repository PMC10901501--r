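---
title: "Validating docked ligand poses: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating docked ligand poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Docking programs and pose-prediction models are usually scored by the
heavy-atom RMSD of a predicted ligand pose against the crystallographic
pose, with a pose counted as a success when the RMSD is at most 2 Å.
RMSD alone says nothing about whether the predicted molecule is still the
molecule that was docked (stereocentres can invert, bonds can be lost in
file round-trips) or whether the geometry is physically sensible (bonds
can be stretched, rings buckled, atoms pushed into the receptor). This
package implements a test suite that judges a pose on three fronts and
reports an aggregate verdict (`pose_valid`) only when every applicable
check passes:

1. **Chemical validity and consistency** — the file loads, the molecule
   sanitises (kekulisable aromatic systems, no valence violations), and
   after standardisation its standard-InChI layers match the reference
   ligand: formula (with net charge `/q` and protons `/p`), bonds
   (connections `/c` with hydrogens `/h`), tetrahedral chirality (`/t`
   with `/m`, `/s`), and double-bond stereochemistry (`/b`).
2. **Intramolecular validity** — bond lengths, bond angles (through the
   1–3 distance surrogate) and non-bonded contacts are checked against a
   distance-geometry bounds matrix; 5/6-membered aromatic rings and
   acyclic C=C units must be planar; and the pose's force-field energy
   must not exceed 100 times the mean energy of an ensemble of 50
   generated conformations.
3. **Intermolecular validity** — minimum-distance ratios and
   volume-overlap shares against the protein and against organic and
   inorganic cofactor groups within 4.0 Å of the ligand.

In addition the package computes symmetry-aware RMSD (minimum over all
graph automorphisms, computed on raw coordinates because re-docked poses
share the receptor frame), RMSD coverage, waterfall summaries that
attribute each failing pose to the first check it fails, and
Smith–Waterman sequence identity for train/test stratification.

## Thresholds

All constants live in `poseval_config()` and every one can be overridden
(per call or through a `key = value` file):

| parameter | default | meaning |
|---|---|---|
| `bond_tolerance`, `angle_tolerance` | 0.25 | pass iff 0.75·lower ≤ d ≤ 1.25·upper |
| `clash_tolerance` | 0.30 | non-bonded pairs must exceed 0.7·lower |
| `planarity_threshold` | 0.25 Å | max deviation from the least-squares plane |
| `energy_ratio_threshold` | 100 | pose energy over ensemble mean (7 = strict calibration) |
| `ensemble_size`, `relax_iterations` | 50, 200 | conformer ensemble size and relaxation cap |
| `distance_factor` | 0.75 | min distance over radii sum (vdW; covalent for inorganic) |
| `overlap_threshold` | 0.075 | max ligand volume share inside the partner body |
| `overlap_scale_organic`, `overlap_scale_inorganic` | 0.8, 0.5 | vdW radius scaling for the overlap bodies |
| `cofactor_cutoff` | 4.0 Å | cofactor proximity window |
| `rmsd_threshold` | 2.0 Å | coverage boundary, inclusive |

## The bounds matrix

The distance-geometry bounds matrix is a deterministic function of the
heavy-atom topology only. Ideal bond lengths are covalent-radius sums
with bond-order factors (1.00 / 0.87 / 0.78 single/double/triple, 0.915
aromatic, which reproduces benzene's 1.39 Å from carbon's 0.76 Å
radius); bonded pairs are bracketed at ±0.06 Å. 1–3 pairs are bracketed
around the law-of-cosines chord of the ideal angle at the central atom
(sp 180°, sp² 120°, sp³ 109.47°, with 104.5° for ether oxygen and 100°
for thioether sulfur), replaced by the polygon interior angle inside
aromatic rings (120°/108°) and small rings (90° for 4-rings, 105° for
5-rings) with widths of 0.10–0.25 Å reflecting how much real rings
pucker. Non-consecutive pairs within one aromatic ring are bracketed by
regular-polygon chords (±0.15 Å), so the benzene para distance 2.78 Å is
bracketed explicitly. All remaining pairs get a van der Waals contact
floor (scaled by 0.8 for 1–4 pairs, where torsional strain legitimately
brings atoms closer) and a loose ceiling, and the matrices are
triangle-smoothed.

Two geometric facts discovered while calibrating the tests are worth
recording. First, a *fully linearised* sp³ angle still passes the 1.25
upper-bound factor: the chord ratio chord(180°)/chord(109.47°) is
1/sin(54.74°) ≈ 1.225 < 1.25. The angle check therefore catches
compressed angles far more readily than opened ones; this is a property
of the published factor, not of this implementation. Second, lifting one
atom of a six-membered ring 0.5 Å out of plane moves the *least-squares*
plane toward it, leaving a maximum deviation of 0.244 Å — just inside
the 0.25 Å planarity threshold. The fixture generator therefore buckles
rings by 0.8 Å (deviation 0.377 Å) for its negative controls.

## The energy ratio

The conformer ensemble is generated from topology alone: classic
metric-matrix distance-geometry embedding (random distance matrix drawn
between the smoothed bounds, Gram-matrix eigendecomposition, top three
eigenvectors), followed by a penalty refinement against the bounds, a
small symmetry-breaking jitter (a perfectly planar embedding has zero
out-of-plane gradient and traps the minimiser), hydrogen completion, and
UFF relaxation by conjugate gradients for up to 200 iterations. Energies
are UFF single-point values in kcal/mol evaluated through the Open Babel
implementation of the force field.

A member counts as *converged* only if (a) its relaxed geometry
satisfies its own bounds matrix and (b) a short further relaxation probe
leaves its energy essentially unchanged; `n_converged ≤ n_requested` is
part of the ensemble contract. The ratio denominator is floored at
ε = 0.01 kcal/mol because UFF means can be arbitrarily close to zero (or
negative for some exotic inputs); flooring is flagged in the check
details. Relaxation uses conjugate gradients because steepest descent at
200 steps leaves distance-geometry embeds visibly unconverged and would
corrupt the denominator.

## Standardisation before InChI comparison

Isotope labels are cleared; formal charges are neutralised by adding or
removing hydrogens where possible (a cation loses a proton it carries, an
anion gains one into an open valence; quaternary ammonium and metal
centres stay charged — with SDF implicit-hydrogen bookkeeping this is
usually just setting the charge to zero). The E/Z label of primary
ketimines (R₂C=NH) depends only on the ambiguous hydrogen position, so
their entries are removed from the `/b` layer using the InChI auxiliary
numbering map. Tetrahedral comparison uses `/t` together with `/m` and
`/s`: inverting the single stereocentre of a molecule flips `/m`, not
`/t`, so comparing `/t` alone would miss full enantiomer swaps. Stereo
specified in exactly one of the two molecules fails the respective check;
this is the stricter of the two readings and is configurable in
principle by comparing layers yourself.

Aromaticity handling is deliberately pragmatic: rings of size 5/6 whose
atoms are all sp²-capable (or lone-pair donors such as pyrrole N and
furan O) are kekulised by a backtracking perfect matching; a molecule
whose aromatic system admits no alternating assignment fails
sanitisation, mirroring the usual cheminformatics behaviour. Extended
polycyclic aromatics beyond fused 5/6-ring systems and charged aromatic
rings (tropylium, cyclopentadienyl) are outside this perception's scope.

## Intermolecular geometry

Distance checks iterate over all heavy-atom pairs; the volume overlap is
integrated on an axis-aligned grid over the ligand's bounding box
(0.25 Å spacing by default). The grid resolves the 7.5% threshold
comfortably: against the analytic two-sphere lens volume the share is
accurate to well under 2% relative error over the whole approach sweep.
Inorganic cofactors use covalent radii for the distance check (metal
coordination bonds are legitimately short) but vdW radii scaled by 0.5
for the overlap check. Ligand atoms covalently bound to the receptor are
not exempted; the 0.75-on-covalent-radii rule already tolerates true
coordination distances. No single radius compilation is canonical for
checks of this kind, so the package ships one self-consistent table
(Bondi/Mantina-style vdW, Cordero-style covalent) in
`inst/extdata/element_radii.tsv`; `radii_table(path)` swaps it out, and
the choice shifts clash ratios by a few percent.

## Sequence identity

Local Smith–Waterman alignment under BLOSUM62 with the affine convention
"first gapped position −11, each extension −1". The implementation runs
on `Biostrings::pairwiseAlignment`, whose `gapOpening`/`gapExtension`
parameterisation differs from that convention; the mapping
(`gapOpening = 10`, `gapExtension = 1`) is pinned by an independent
dynamic-programming oracle in the test suite over hundreds of random
pairs. Identity is exact matches over the *query* length (asymmetric by
design), unknown residues map to X and never count as matches, and the
bins are low [0, 30), medium [30, 90], high (90, 100] — the printed
interval boundaries 30 and 90 both fall in medium.

## The synthetic fixture generator

The generator emulates exactly the features the checks measure: 15
drug-like toy templates (aromatics, heteroaromatics, chains, a chiral
alcohol, cis/trans alkenes, an amide, an ester, a carboxylate) embedded
and relaxed into valid conformers; ten distortion kinds each designed to
trip one named check (bond stretch/compress ×1.4/×0.6, angle bend to
60°, ring buckle 0.8 Å, double-bond twist 90°, stereo flip by reflection
through the molecule's own best-fit plane so that geometry is preserved
and the RMSD to the original stays below 2 Å, chain fold, rigid clash
translation, element mutation, bond rewiring with re-embedding); and a
toy complex consisting of an idealised 8-residue polyalanine helix, a
Zn²⁺ ion and an acetate group placed in the 3.0–4.0 Å proximity window,
and a ligand pose at least 3.5 Å from every receptor atom.

Known entanglements on the defect–detector grid: a bond stretch also
moves the 1–3 surrogate distances at large magnitudes (the default 1.4
is chosen to isolate the bond check); a 90° double-bond twist also
changes perceived E/Z stereo; element mutation changes the InChI
connection layers along with the formula. These are physical couplings,
not detector faults.

What passing these tests does *not* show: the toy receptor has no real
binding pocket, no rotamer diversity and no crystallographic noise; the
templates are small and rigid compared to real drug-like ligands (no
macrocycles, no fused polycyclics, no charged aromatics); and UFF is a
generic force field. Results on real docking outputs depend on input
files that respect the format conventions this package parses (V2000/
V3000 SDF with `M CHG`/`M ISO`, PDB with sensible residue naming).

## Problem sizes in the shipped tests

The test suite exercises 15 templates × 20 seeds for the soundness
property, 20-conformer ensembles per template (50 is the production
default), 200 random sequence pairs against the alignment oracle, and
exhaustive isomorphism enumeration for molecules up to 12 heavy atoms —
sizes chosen so the whole suite runs in a few minutes on one CPU while
still exercising every code path. `scripts/acceptance.R` recomputes the
same quantities from scratch at 15 × 5 seeds.
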