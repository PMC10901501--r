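# poseval

Physical validity checks for docked protein–ligand poses.

## Why

Docking methods — classical and deep-learning-based alike — are scored
almost exclusively by heavy-atom RMSD to the crystal pose, counting a
prediction as correct when RMSD ≤ 2 Å. That criterion is blind to two
failure classes that matter in practice: the predicted molecule may no
longer be the docked molecule (inverted stereocentres, lost bonds,
changed protonation), and the geometry may be physically impossible
(stretched bonds, buckled aromatic rings, internal clashes, ligands
embedded in the protein). `poseval` runs a pose through 18 checks in
three groups and calls it valid only when every applicable check passes:

**Chemical validity and consistency** — the record parses; the molecule
admits an octet-complete Lewis structure (kekulisation + valence);
and after neutralising charges and stripping isotopes, the standard-InChI
layers match the reference ligand: formula + `/q` + `/p`, connections
`/c` + hydrogens `/h`, tetrahedral `/t` (+`/m`,`/s`), double-bond `/b`.

**Intramolecular validity** — with `lower`/`upper` from a
distance-geometry bounds matrix built from topology alone:

- bond lengths and 1–3 (angle) distances inside `[0.75·lower, 1.25·upper]`,
- non-bonded pairs above `0.7·lower`,
- 5/6-membered aromatic rings and acyclic C=C units within 0.25 Å of
  their least-squares plane,
- UFF energy of the pose at most 100 × the mean of an ensemble of 50
  distance-geometry conformers relaxed for up to 200 iterations.

**Intermolecular validity** — against the protein and any cofactor
group within 4.0 Å of the ligand: minimum distance above 0.75 × the sum
of vdW radii (covalent radii for inorganic cofactors such as metal
ions), and ligand volume-overlap share below 7.5% with radii scaled by
0.8 (protein, organic cofactors) or 0.5 (inorganic).

The package also computes symmetry-aware RMSD (minimum over graph
automorphisms, no re-superposition), coverage at 2 Å, waterfall
summaries (first-failure attribution), and Smith–Waterman/BLOSUM62
sequence identity (gap open −11, extend −1, query-length denominator)
with low/medium/high binning. A fixture module generates toy complexes
and targeted single-defect distortions, so the entire suite tests itself
without downloading any structure.

## Worked example

```r
library(poseval)

tc <- make_toy_complex(seed = 11, dir = "demo")        # receptor.pdb, true.sdf, pred.sdf
flip    <- distort(tc$ligand, "stereo_flip")           # inverted stereocentre, geometry intact
stretch <- distort(tc$ligand, "bond_stretch")          # one bond scaled by 1.4
writeLines(write_sdf(list(tc$ligand, flip, stretch)), "demo/pred3.sdf")

res <- bust("demo/pred3.sdf", "demo/true.sdf", "demo/receptor.pdb")
bust_table(res)[, c("pose", "tetrahedral_chirality", "bond_lengths",
                    "rmsd", "rmsd_within_threshold", "pose_valid")]
#>       pose tetrahedral_chirality bond_lengths      rmsd rmsd_within_threshold pose_valid
#> 1 butan2ol                  TRUE         TRUE 0.0000000                  TRUE       TRUE
#> 2 butan2ol                 FALSE         TRUE 0.4099322                  TRUE      FALSE
#> 3 butan2ol                  TRUE        FALSE 0.2733058                  TRUE      FALSE

waterfall(res)
#> <waterfall_summary> 3 pose(s), 1 pass all checks
#>                  check failures_introduced
#>  tetrahedral_chirality                   1
#>           bond_lengths                   1
```

All three poses sit well inside the 2 Å RMSD criterion — by the usual
docking metric they are all "correct". Only the first is actually the
right molecule in a physically sensible conformation: the second is the
enantiomer at the ligand's stereocentre (RMSD 0.41 Å!), the third
carries a stretched bond. That gap between RMSD and validity is the
point of the suite.

Command-line use (thin wrappers over the same functions):

```sh
Rscript inst/scripts/poseval-cli.R pred.sdf true.sdf receptor.pdb --outfmt short --out report.csv
Rscript inst/scripts/fixtures-cli.R --out fixtures --seed 7
```

Every threshold can be overridden with `--config file` (`key = value`
lines; see `?poseval_config` for the keys and defaults).

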