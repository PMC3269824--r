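---
title: "Methods: conformer models and Gaussian 3-D similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer models and Gaussian 3-D similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pubshape3d)
```

`pubshape3d` implements the archive-style pipeline that turns a small
organic molecule into a bounded set of representative 3-D conformers and
compares such sets by three-dimensional shape and pharmacophore
similarity. This vignette is the package's own account of the underlying
models, the parameters that matter, and the numerical choices made where
the design was genuinely open.

## Coverage rules and the effective rotor count

A molecule receives a conformer model only when a 3-D description is both
feasible and meaningful. Six rules gate entry, all evaluated by
`check_eligibility()` and all configurable through `eligibility_config()`:
at most 50 non-hydrogen atoms; at most 15 rotatable bonds; only the
elements H, C, N, O, F, Si, P, S, Cl, Br, I; a single covalent unit (no
salts or mixtures); atoms typeable by an MMFF94s-style force field; and
fewer than six undefined stereocenters. Every violated rule is reported,
not just the first.

Flexibility is summarized by the *effective rotor count*

$$er = rb + nara/5,$$

where $rb$ counts single, non-ring, non-terminal bonds between heavy
atoms (amide C–N bonds excluded under the default, switchable convention)
and $nara$ counts atoms in non-aromatic rings excluding bridgeheads and
sp2-hybridized atoms — a ring's partial flexibility is worth one fifth of
a rotor per eligible atom.

Three perception rules had to be pinned down because no published
definition exists at this level of detail, and each is a documented,
deliberate choice rather than a claim of parity with any production
system: aromaticity honors the input SDF aromatic bond flag and otherwise
uses Kekulé alternation on even-sized rings of sp2 C/N/O/S atoms;
a bridgehead is an atom with three or more ring bonds; rotatable-bond
"IsRotor" semantics follow the common medicinal-chemistry convention.
Stereocenter perception is *not* implemented: `undefined_stereo_count` is
a declared input (read from SDF when present, default 0) because no
installed toolkit in this stack perceives stereogenicity, and guessing
would be worse than declaring.

## Sampling RMSD and ensemble reduction

The resolution at which an ensemble is sampled scales with size and
flexibility:

$$\mathrm{RMSD}_{pred} = 0.219 + 0.0099\,nha + 0.040\,er
\;(\unicode{xC5}),$$

rounded to the nearest 0.2 Å increment and floored at 0.4 Å
(`predict_sampling_rmsd()`). Ties at the midpoint round *up*: a coarser
sampling is the conservative, deterministic choice. If more than 500
conformers survive sampling, the RMSD is incremented by 0.2 Å and the
ensemble re-clustered until the model holds at most 500
(`build_conformer_model()`).

Dissimilarity is the heavy-atom RMSD minimized over rigid superposition
(Kabsch) and, optionally, over graph automorphisms of the heavy-atom
subgraph so that, e.g., a flipped phenyl ring does not inflate the
distance. Automorphism groups are expanded from igraph's generators by
breadth-first products under a configurable budget (default 2000); when
the group is larger, the identity mapping is used instead — symmetry
search is an accuracy refinement, never a correctness requirement.

`sample_ensemble()` visits conformers in ascending energy (ties by input
order), so the lowest-energy conformer always survives, and works in two
stages: a partition pass over an exclusion-region hierarchy of radii
$4r \to 2r \to r$ (the paperless constants: a geometric sequence was
chosen because only "decreasing dissimilarity" is specified), then a
quadratic pass over the stage-one representatives to remove partition
edge effects, and finally a coverage sweep that promotes any conformer
left farther than $r$ from every retained one. The result therefore
satisfies both guarantees *exactly*: every input conformer lies within
$r$ of a retained one, and retained conformers are pairwise at least $r$
apart. Conformer generation itself (torsion driving, energy windows,
stereoisomer enumeration) is a pluggable backend contract
(`generator_config()`: 25 kcal/mol window, 100,000 conformers per
stereoisomer); the package never re-implements it, and the hydrogen
relaxation and force-field "bump" check of the production pipeline are
likewise backend post-processing hooks outside the tested math core.

## Gaussian shape: volumes, moments, canonical frames

Each heavy atom contributes a spherical Gaussian of height $p = 2.7$
whose exponent is calibrated so an isolated atom's Gaussian volume equals
its hard-sphere volume $\tfrac43\pi R^3$ (the classic soft-sphere
construction). Radii default to familiar van der Waals values (C 1.70 Å,
N 1.55 Å, O 1.52 Å, ...); a `carbon_radius_mode` treats all heavy atoms
as carbon for element-blind searches. Molecular volume is the
inclusion–exclusion sum over atom subsets truncated at a configurable
order (default pairwise; up to order 6). The truncation bias is real and
documented: on a dense three-atom triangle the pairwise volume
undercounts the full sum by roughly 10%, which is why the suite's 2%
grid-integration oracle is applied at full order and the pairwise path is
tested against its own documented tolerance.

Two distinct "self" quantities coexist by design. The *conformer volume*
(`self_volume()`) is the union volume above. The *shape self-overlap*
(`self_overlap_volume()`) is the Gaussian density overlapped with itself,
the quantity the shape Tanimoto needs:

$$ST = \frac{V_{AB}}{V_{AA} + V_{BB} - V_{AB}},$$

with `overlap_volume()` defined as $V_A + V_B - V_{A\cup B}$ at the
configured order — at pairwise order this reduces exactly to the
cross-term sum of Gaussian product integrals. Using self-overlaps in the
denominator makes $ST(A,A) = 1$ an identity rather than an
approximation. The two self quantities agree only in the weak-overlap
limit, which is precisely why both are stored as separate conformer
properties.

Steric multipoles (`steric_moments()`) are analytic moments of the same
truncated Gaussian density about the heavy-atom steric center: monopole
(volume, Å³), diagonal second moments ordered $Q_x \ge Q_y \ge Q_z$
(Å⁵: length, width, height), and the ten third moments (Å⁶). Density
moments, not hard-sphere moments, were adopted — the Å⁵ units of the
published quadrupole examples are consistent with density second moments.

`canonicalize_principal_axes()` puts the heavy-atom centroid at the
origin and aligns the unit-weight (non-mass-weighted) principal inertia
axes with x = longest extent. Sign conventions matter for reproducible
fingerprints: each axis is flipped so its heavy-atom third moment is
non-negative, and if that leaves an improper frame the axis with the
smallest third-moment magnitude is flipped back, giving a deterministic
proper rotation. Degenerate spectra (spherical or symmetric tops) fall
back to the numerically stable eigendecomposition order; the convention
is arbitrary but stable, which is all downstream replay needs.

## Superposition optimization and color features

`optimize_overlap()` performs rigid-body (6-DOF) local optimization of
the overlap objective using derivative-free Nelder–Mead over a rotation
vector plus translation, started from the four proper sign-flip poses of
the two canonical frames, keeping the best optimum and never reporting a
pose worse than its starting grid. In shape mode the objective is
$V_{AB}$; in feature mode it is the total same-type color-atom overlap.
The color Tanimoto is always a single-point evaluation at the final pose,
matching the ST-optimized-overlay-then-CT protocol, and
$ComboT = ST + CT$ holds exactly by construction.

The six feature types (anion, cation, acceptor, donor, hydrophobe, ring)
are perceived by an explicit, inspectable rule set evaluated at an
assumed pH-7 protonation state (`feature_rules()`): carboxylate,
sulfonate and phosphate heads plus bare negatively charged O/S/N are
anions; positively charged nitrogens, non-amide sp3 amines and
amidine/guanidine groups are cations; oxygens and lone-pair nitrogens
accept; O–H and N–H (explicit or implicit hydrogens) donate; connected
groups of three or more apolar carbons/halogens are hydrophobes; every
minimum-cycle-basis ring is a ring feature. Same-type features within
1.0 Å merge iteratively, positions recomputed from the merged member
atoms (merged positions, not original ones, drive any cascade), with a
deterministic (type, lowest atom index) tie-break. Color atoms are
1.0 Å Gaussians of the same height as shape atoms; since feature sets are
sparse, plain product-overlap sums are used and $CT(F,F) = 1$ exactly.
Two featureless conformers score $CT = 0$ by convention — the neighboring
rules handle that case with a separate shape-only threshold, so crediting
an empty match would double-count.

## Diverse ordering, fingerprints, neighboring

The diverse conformer ordering (`diverse_order()`) starts at the
lowest-energy conformer (ties by local id) and greedily picks the
conformer with the smallest summed ComboT to the already-assigned set,
breaking ties by the largest summed ComboT to the unassigned set, then by
the smallest local id. The second pick is simply the rule's first
application. The ordering is a separate, explicit step rather than an
implicit part of model building because it costs a quadratic number of
pose optimizations.

Shape fingerprints (`fingerprint_conformer()`) record, for each reference
shape exceeding an ST threshold (default 0.8; the production threshold is
unpublished, so no parity is claimed), the reference GID plus the
aligning transform packed into 64 bits: a 2-bit smallest-three index,
three 14-bit quaternion components scaled by $\sqrt2$, and three 6-bit
translation components on a 0.25 Å grid spanning ±8 Å. Reference sets are
built by greedy leader clustering (`build_reference_set()`) so no two
references exceed the construction threshold to each other, with 50 Å³
analytic-volume bins as search metadata. A Cauchy–Schwarz bound on ST
from the self-overlaps prunes hopeless comparisons exactly.
`recycle_alignment()` composes the two stored alignments through a common
reference into a direct pose: pairs with no common bits are skipped
outright, and replayed scores are single-point evaluations that cannot
meaningfully exceed the fully optimized ST.

Neighboring (`neighbor_search()`) scores the first three diverse
conformers per compound (configurable to ten) and applies strict
thresholds: featured pairs neighbor when $ST > 0.795$ and $CT > 0.495$;
featureless pairs when $ST > 0.925$; mixed pairs never — the published
rules cover only the homogeneous cases, and the conservative resolution
of the mixed case is this package's documented choice. Threshold equality
is not a neighbor. The corpus may be split into any number of evenly
sized shards with set-identical results, each unordered pair emitted once
with $gid_a < gid_b$. Score matrices (`score_matrix()`) default to the
best-ComboT conformer pair per compound pair with a 10^6 conformer-pair
request budget, and `single_linkage_cluster()` cuts the resulting
similarity graph at a threshold (4,000-compound cap).

## Identifiers

A global conformer identifier packs `(structure id, version, local id)`
into 64 bits: the low 16 bits are the local conformer id, the next 16 the
version (zero for compound conformers, nonzero for deposited substance
conformers), the high 32 the CID or SID. R has no native 64-bit unsigned
integer, so GIDs are zero-padded 16-digit hex strings throughout
(`encode_gid()` / `decode_gid()`), a bijection tested over 10^4 random
triples.

## What the synthetic generator emulates — and what it does not

`synthetic_ensemble()` produces carbon-chain "molecules" whose conformers
are jittered, rigidly displaced copies of a few well-separated base point
clouds, with energies increasing in draw order. This emulates exactly the
structure the sampling and neighboring machinery must handle — duplicate
groups below the sampling radius, rigid motions that superposed RMSD must
remove, known ground-truth group counts — and nothing else. It does not
emulate torsional correlation, force-field energy landscapes, realistic
atom typing, or feature chemistry; the hand-built toy panel
(`toy_panel()`, including a catecholamine with explicit hydrogens whose
coordinates were generated once with Open Babel and frozen) covers the
chemistry-dependent paths. Passing tests on these fixtures therefore
demonstrates the correctness of the sampling, scoring and bookkeeping
machinery, not the realism of any conformer generator, which is
explicitly out of scope.

Default generator settings used by the test and acceptance workloads:
duplicate-group recovery uses 5 groups x 10 copies with 0.05 Å jitter
(well below the 0.4 Å sampling floor, so exact recovery is the designed
outcome); the large re-clustering demonstration uses 5,000 conformers
(50 groups x 100 copies at 0.08 Å jitter) of a hexane-like chain; oracle
comparisons run at 20–50 conformers where an $O(N^2)$ brute force is
exact and fast. These sizes keep the full suite within a ten-minute
single-CPU envelope while leaving every algorithmic branch exercised.

## Numerical choices and known limitations

* Optimizer: Nelder–Mead with `reltol` 1e-8, at most 300 iterations per
  start, 4 starts. A 5°-step rotation-grid oracle in the suite confirms
  the optimizer lands within 0.02 ST of the grid optimum on toys.
* Pairwise truncation is the default volume model; orders above 2 grow
  combinatorially and are intended for small molecules and validation.
* The transform codec quantizes translations to 0.25 Å; replayed poses
  are meant to seed or skip optimization, not to replace it when exact
  poses matter.
* RMSD-based sampling assumes a consistent atom ordering between
  conformers of one molecule (true for any single-source ensemble).
* Feature perception is rule-based and pH-naive; tautomers, explicit pKa
  and aromatic subtleties beyond the documented model are out of scope.
* Archive-scale corpus statistics (coverage percentages, 81-million
  conformer searches, the 740k-molecule random-similarity distribution)
  require the archive and its proprietary generation stack; the package
  reproduces the *rules* and desk-scale checks, and
  `random_similarity_study()` estimates the score statistics on any
  corpus generator you supply.
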