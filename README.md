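# pubshape3d

Conformer models and 3-D similarity for small molecules, in R.

Medicinal chemists routinely need to ask whether two chemical structures
can *look alike in three dimensions* even when their 2-D graphs are
dissimilar — the question behind scaffold hopping, off-target prediction
and 3-D neighboring of compound archives. `pubshape3d` implements the
full desk-scale pipeline for that question:

* **Coverage rules** deciding which molecules receive a conformer model
  (≤ 50 heavy atoms, ≤ 15 rotatable bonds, supported elements, single
  covalent unit, force-field-typeable atoms, < 6 undefined
  stereocenters).
* **Sampling**: the resolution model
  `RMSD = 0.219 + 0.0099·nha + 0.040·er` (rounded to 0.2 Å, floored at
  0.4 Å) with `er = rb + nara/5`, symmetry-aware heavy-atom RMSD, and
  two-stage exclusion-region clustering capping every model at 500
  conformers.
* **Gaussian shape**: analytic soft-sphere volumes, steric multipole
  moments, principal-steric-axes canonicalization.
* **Similarity**: rigid-body superposition optimization maximizing
  volume overlap, scored as shape Tanimoto
  `ST = V_AB / (V_AA + V_BB − V_AB)`, color (pharmacophore-feature)
  Tanimoto `CT` over six feature types, and `ComboT = ST + CT`.
* **Diverse conformer ordering**, **shape fingerprints** with 64-bit
  packed alignments and alignment recycling, **64-bit global conformer
  identifiers**, and a **"similar conformers" neighboring engine**
  (ST > 0.795 & CT > 0.495 featured / ST > 0.925 featureless, strict)
  with shard-parallel search, score matrices and single-linkage
  clustering.
* **SDF I/O** for the `PUBCHEM_*` property-tag dialect and neighbor-pair
  flat files, plus deterministic fixture generators.

## Worked example

A catecholamine from the built-in toy panel, end to end:

```r
library(pubshape3d)

dp <- toy_dopamine()
check_eligibility(dp$molecule)
#>   record_id eligible nha rb nara er
#> 1       681     TRUE  11  2    0  2
predict_sampling_rmsd(11, 2)
#> [1] 0.4
```

Eleven heavy atoms and two rotors give an effective rotor count of 2 and
a sampling RMSD at the 0.4 Å floor: retained conformers of this molecule
are guaranteed to be at least 0.4 Å apart (heavy-atom, symmetry-aware,
superposed RMSD).

```r
cc <- canonicalize_principal_axes(dp$conformer)
self_volume(cc, mol = dp$molecule)
#> [1] 95.03
feature_counts(perceive_features(dp$molecule, dp$conformer))
#>  anion  cation  acceptor  donor  hydrophobe  ring
#>      0       1         2      3           0     1
```

The analytic Gaussian volume is 95.03 Å³, and the feature rules find the
protonatable amine (cation), the two phenol oxygens (acceptors), three
O–H/N–H donors and the aromatic ring. Shape-optimizing a rigidly moved
copy recovers the pose:

```r
moved <- conformer(dp$conformer$coords %*% t(R) + 2, molecule = dp$molecule)
optimize_overlap(dp$conformer, moved, mol_a = dp$molecule, mol_b = dp$molecule)
#> <similarity_result> ST 1.0000  CT 1.0000  ComboT 2.0000
conformer_gid(dp$molecule, dp$conformer)
#> [1] "000002A900000000"
```

`ST = CT = 1` (so `ComboT = 2`) says shape and features superimpose
perfectly — the pair would pass the featured neighboring thresholds with
room to spare. The hex string is the 64-bit global conformer id packing
structure id 681, version 0 and local id 0.

Results surface as tibbles (`tidy()`, `glance()`) and plots
(`autoplot()` on score matrices and random-similarity studies); a thin
command-line front end lives in `inst/cli/pubshape3d.R`.

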