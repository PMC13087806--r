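# nahdesign

Reaction-driven design and SAR analytics for *N*-acylhydrazone (NAH) kinase
inhibitor libraries.

The Rho-associated kinases ROCK1/ROCK2 are ATP-site drug targets in cancer
and fibrosis, and the *N*-acylhydrazone motif R–C(=O)–NH–N=CH–R′ is a
synthetically trivial linker between a hinge-binding heteroaromatic and a
terminal aromatic that reaches the kinase affinity pocket. `nahdesign`
implements the computational workflow that discovers such inhibitors from a
reagent collection, for medicinal and computational chemists who want each
stage reproducible and testable in R:

1. **Curation** — salt stripping to the largest organic fragment,
   neutralization, functional-group role assignment (carboxylic acid /
   aldehyde / other), deduplication by canonical structure.
2. **Virtual synthesis** — two two-component reaction transforms applied at
   every matching site:
   `[#6:1](=[#8:2])[O:3].[#7:4][#7:5]>>[#6:1](=[#8:2])[#7:4][#7:5]`
   (acid + hydrazine → hydrazide) and
   `[#6:1](=O)[N:2][N:3].[#6:4][C:5]=O>>[#6:1](=O)[N:2]/N=[C:5]/[#6:4]`
   (hydrazide + aldehyde → *E*-configured hydrazone).
3. **Prioritization** — descriptor filter (Fsp3 = #C(sp³)/#C ≥ 0.1,
   stereocenters = 0), 1024-bit circular fingerprints (diameter 4), and a
   chemical-space embedding: Z-score → 2-component PCA → min–max scaling to
   [0, 1]².
4. **Verification** — molecular formula, monoisotopic mass and ion-adduct
   m/z ([M+H]⁺, [M−H]⁻, [M+Na]⁺, [M+Cl]⁻ with electron-mass correction)
   reproducing calculated HRMS values to 5 decimals; pharmacophore
   constraint checking of 3D poses against hydrogen-bond acceptor/donor
   spheres in the kinase ATP site.
5. **Pharmacology analytics** — fold potency/selectivity ratios from IC50
   tables, Cheng–Prusoff conversion K_i = IC50 / (1 + [ATP]/K_m), off-target
   kinase-panel summaries, matched-pair (homologation / bioisostere) SAR
   reports, and PAMPA permeability classification (GIT bands by absorbed
   fraction: high 70–100%, medium 30–69%, low; BBB bands by Pe in 10⁻⁶ cm/s:
   CNS+ ≥ 4.0, CNS− < 2.0, CNS± between).

A seeded synthetic reagent-collection generator with planted ground truth
(salts, duplicates, stereocenter decoys, low-Fsp3 decoys) makes the whole
pipeline testable end to end without external data.

## Worked example

Enumerate the bundled reference building blocks (4 acids × 9 aromatic
aldehydes) and inspect the 7-azaindole product:

```r
library(nahdesign)
fx  <- reference_fixtures()
lib <- enumerate_library(fixture_blocks(fx))
length(lib)
#> [1] 36

key12 <- mol_parse(fx$products$smiles[fx$products$id == "12"])$canonical_key
cmp <- lib[[which(library_keys(lib) == key12)]]
cmp
#> <nah compound> NAH00015 (C19H17N5O; acid 26 + aldehyde 11)
#>   O=C(CCc1c[nH]c2c1cccc2)NN=Cc1c[nH]c2c1cccn2
cmp$descriptors
#> C19H17N5O  M = 331.14331 Da  Fsp3 = 0.1053  stereocenters = 0

sprintf("%.5f", adduct_mz(cmp$mol, "[M+H]+"))   # calculated HRMS
#> [1] "332.15059"

length(apply_filters(lib))   # Fsp3 >= 0.1, no stereocenters
#> [1] 24
```

The enumerated set contains all 13 synthesized derivatives of the congeneric
series by canonical equality, and the descriptor/mass layer reproduces their
calculated HRMS anchors. The analytics layer works off the bundled assay
tables:

```r
rec <- potency_records("rock")
as.numeric(fold_ratio(rec, 13, 12, "ROCK1"))  # potency gain of compound 12
#> [1] 452
cheng_prusoff_ki(0.051)       # IC50 51 nM at [ATP]=1 uM, Km=10 uM
#> [1] 0.04636364
classify_pampa("BBB", pe = 2.453)
#> [1] "CNS+/-"
```

A command-line surface over the same functions lives in
`inst/cli/nahtools.R` (subcommands `enumerate`, `pipeline`, `masscalc`,
`sar`, `pampa`, `verify`, `synth`).

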