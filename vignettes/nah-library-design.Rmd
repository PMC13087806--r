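---
title: "Designing N-acylhydrazone kinase-inhibitor libraries: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing N-acylhydrazone kinase-inhibitor libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nahdesign)
```

## The design problem

*N*-acylhydrazones (NAH, R–C(=O)–NH–N=CH–R′) are condensation products of an
acylhydrazide and an aldehyde. As kinase-inhibitor scaffolds they place a
hinge-binding heteroaromatic on the imine side and a terminal aromatic on
the acyl side, joined by a linker whose length and sp³ content control how
the two ends sit in the ATP site. `nahdesign` models the discovery loop
around this chemistry: enumerate every NAH accessible from a reagent
collection, keep the flexible achiral candidates, map them in chemical
space, verify identities by exact mass, and quantify the resulting
structure-activity and permeability data.

## Virtual synthesis

Two reaction transforms (`reaction_rules()`) define the chemistry:

* **Hydrazide formation** `[#6:1](=[#8:2])[O:3].[#7:4][#7:5]>>[#6:1](=[#8:2])[#7:4][#7:5]`.
  Hydrazine is the fixed second component; its two nitrogens are equivalent,
  so no site explosion occurs on that side. The transform condenses the
  esterification/substitution sequence of the bench route into one step,
  which is what a virtual two-component reaction node does.
* **Hydrazone formation** `[#6:1](=O)[N:2][N:3].[#6:4][C:5]=O>>[#6:1](=O)[N:2]/N=[C:5]/[#6:4]`.
  The aldehyde template requires a carbon substituent on the carbonyl, so
  formaldehyde is deliberately not a match.

The transforms are applied as connection-table edits at **every**
combination of matching sites, one site at a time (no double
condensations); products are sanitized, canonicalized and deduplicated.
Symmetric multi-site reactants therefore collapse: succinic acid gives one
unique monohydrazide, methylsuccinic acid two.

Site perception is deliberately narrow. A carboxylic-acid site is a
carbonyl carbon bearing a terminal `=O` and a terminal neutral `–OH`, with
no further O/N/S substituent on the same carbon — carbamic and carbonic
acids, esters and amides do not react, matching the scope of the bench
chemistry (Fischer esterification followed by hydrazinolysis).

**Geometry.** The condensation is run under thermodynamic control and the
new C=N bond is emitted *E*-configured. Canonical keys, however, are
computed from the coordinate-free connection table, so they are
constitution-level; the *E* flag travels as molecule metadata and as an SD
tag on export. No two products of the enumeration differ only in C=N
geometry under forced-*E*, so set-level uniqueness is unaffected. This also
prevents a subtle artifact: canonical SMILES derived from depicted 2D
coordinates would otherwise acquire accidental cis/trans descriptors.

## Descriptors and the prioritization filter

* **Fsp3** = (number of sp³ carbons) / (number of carbons), the standard
  carbon-only definition. On a kekulized connection table an sp³ carbon is
  one with only single bonds. A carbon-free molecule reports 0 with a
  `carbon_free` flag.
* **Stereocenters** are potential or assigned tetrahedral carbons: sp³, at
  most one hydrogen, four constitutionally distinct substituents. Because
  the library is 2D at filter time, distinctness is decided by Morgan-style
  graph-refinement symmetry classes, which counts unassigned centers too.
  The hydrazone C=N axis is *not* a stereocenter. The refinement
  approximates graph automorphism; pathological para-stereocenters
  (pseudo-asymmetry) are outside its scope and outside this chemistry.
* **Defaults** (`filter_spec()`): Fsp3 ≥ 0.1 and 0 stereocenters. The
  threshold keeps candidates with at least minimal aliphatic character —
  with the bundled building blocks the two-methylene and trimethoxyphenyl
  products pass while the fully aromatic products fail. Of the bundled
  reference products, the one-methylene homologues (ids 17–20, Fsp3 1/18 to
  1/14) sit *below* the default floor: they were designed by homologation
  from the filtered hits, not selected from the filtered library, and the
  tests assert exactly that behaviour.

## Exact masses and ion adducts

Monoisotopic masses are summed from a versioned isotope table
(`inst/extdata/isotope_masses.csv`, most-abundant-isotope masses to ≥ 6
decimals). Adduct m/z values add the species delta with electron-mass
correction: an electron (as 5.5e-4 Da) is removed for cations and added for
anions. The 5-decimal electron mass matches the precision at which
high-resolution calculated masses are conventionally reported, and it is
the convention under which the bundled reference HRMS values are reproduced
at all five printed decimals. Two bundled reference values are flagged in
the fixture table itself: the [M+Cl]⁻ anchor of product 16 is inconsistent
with its own formula by ~0.9 mDa, and the [M+H]⁺ anchor of product 19 sits
one 5th-decimal unit above the table arithmetic; both are recorded as
notes, not used as test anchors.

## Fingerprints and the chemical-space embedding

`ecfp4()` is an extended-connectivity fingerprint of diameter 4 folded to
1024 bits: per-atom seed invariants (element, heavy degree, hydrogen count,
formal charge, ring membership) are grown through two rounds of
neighbourhood hashing, and every environment identifier sets `id mod 1024`.
Bit positions are specific to this implementation's hash; determinism
within the package is guaranteed and tested, bit-compatibility with other
toolkits is not promised (similarity *orderings* are what the embedding
consumes).

`fit_embedding()` drops constant bits (their Z-score is undefined — the
only well-defined choice), standardizes the rest, and takes the top two
principal components of the standardized matrix; on standardized data the
covariance and correlation routes coincide, and the test suite pins the
result against an explicit dense eigendecomposition to 1e-6. Two
conventions make runs reproducible: each component is sign-flipped so its
largest-magnitude loading is positive, and min–max scaling uses the score
ranges stored at fit time, so the fitted set spans exactly [0, 1] on each
axis. Held-out projections may leave [0, 1]; they are reported **unclamped**
with an `out_of_range` flag, because silently clamping would fabricate
coordinates on the hull.

## Pharmacophore constraint checking

`default_pharmacophore()` carries the two ATP-site constraint spheres used
for docking prioritization — a hydrogen-bond acceptor sphere (radius 0.7 Å)
at (34.740, 4.823, −70.239) and a donor sphere (radius 1.0 Å) at (32.837,
5.358, −71.278) in the receptor frame, both with weight 10. A point is
satisfied when at least one atom of the matching class lies within its
radius, **inclusive**; the check is rigid-motion invariant (tested under
random rotations plus translations). Constraint weights parameterize the
docking score of the downstream engine, which is out of scope here, so they
are metadata only.

Feature typing for poses is simplified and stated in the reader: acceptors
are any oxygen plus hydrogen-free nitrogens (pyridine-type lone pairs);
donors are N/O bearing at least one hydrogen. This misses exotic cases
(thiocarbonyls, charged tautomers) but is exact for the heteroaromatics
this chemistry produces.

## Pharmacology analytics

* `fold_ratio()` divides unrounded stored IC50s; display rounding is two
  significant figures, kept separate from the raw ratio. Published fold
  claims are conservative roundings (e.g. a 22.4 ratio reported as
  "21-fold"), so acceptance-style checks treat them as lower bounds.
  Extrapolated IC50s (including % max-inhibition-derived estimates) carry
  an `extrapolated` flag and are excluded unless explicitly allowed in.
* `cheng_prusoff_ki()` implements K_i = IC50 / (1 + [ATP]/K_m) for
  ATP-competitive inhibition, default [ATP] = 1 uM against K_m = 10 uM (the
  sub-K_m assay regime in which IC50 ≈ K_i); `ki_to_ic50()` is its exact
  inverse.
* `classify_pampa()` bands: the printed BBB bands overlap at Pe = 4.0
  (CNS+ "≥ 4.0" and CNS± "≤ 4.0"); the affirmative CNS+ call wins there,
  the ± band being the method's uncertainty range. The GIT bands leave a
  printed gap between 69 and 70%; values in (69, 70) classify as medium,
  i.e. boundaries are inclusive on the low edge of each band. The absorbed
  fraction Fa% is an assay-derived input — no Pe→Fa formula is assumed.
* `panel_summary()` excludes ROCK1/2 from "off-target" by definition and is
  a pure transcription-driven summary; the bundled assay tables are guarded
  by checked-in checksums.

## The synthetic reagent generator

`generate_library()` emulates what matters about an in-house reagent
collection for *this* pipeline: aryl/heteroaryl carboxylic acids with
aliphatic linkers, aromatic aldehydes, sodium-carboxylate salt spellings,
exact duplicates, α-methyl (one stereocenter) acids and fully aromatic
acids. Every acid template is constructed so the Fsp3 of each of its future
products is known analytically from carbon counts — that is how the
expected filter-pass counts are fixed *during construction* rather than
measured afterwards, keeping the ground truth independent of the code under
test. The generator does not emulate the size or compositional diversity of
a real collection (no tautomers, no protecting groups, no reagent-grade
impurities beyond salts), so passing counts demonstrate the pipeline's
bookkeeping and chemistry on clean single-site blocks, not performance on a
production reagent file.

Test problem sizes are a package choice balancing coverage against runtime:
20 seeds × (10 acids × 4 aldehydes with 20% salt/duplicate/stereo/low-Fsp3
fractions) for the end-to-end count identity, 50 × 1024 bit matrices for
the embedding oracle, and 40 labeled poses for the checker.
`generate_poses()` places feature atoms inside constraint spheres (at ≤ 0.85
of the radius) or parks them ≥ 8 Å away, so planted labels are
unambiguous by construction; all generators use one local seeded stream and
restore the global RNG state.

## Numerical conventions and limitations

* Masses are reported to 5 decimals, embedding coordinates to 4 — fixed
  precision keeps repeated runs diff-stable.
* Canonicalization and SMILES parsing are delegated to OpenBabel through
  `ChemmineOB`; the connection-table layer on top (valence model, implicit
  hydrogens, site perception, graph edits) is this package's own and is
  cross-checked against the toolkit's formulas and exact masses in the test
  suite.
* The valence model covers ordinary organic chemistry (B, C, N, O, S, P,
  halogens; ±1 charges; hypervalent S/P promotion). Organometallics beyond
  simple counterions are out of scope.
* Docking itself, binding-site preparation, conformer generation and
  tautomer enumeration are out of scope; poses enter as SDF with 3D
  coordinates from whatever engine produced them.
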