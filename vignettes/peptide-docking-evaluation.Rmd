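---
title: "Evaluating peptide-protein complex predictions with PepDockBench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating peptide-protein complex predictions with PepDockBench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PepDockBench)
```

## The problem and the approach

Short peptides (here 4–25 residues) bind protein receptors through
interfaces that look, structurally, like the last step of the receptor's own
folding: the peptide complements a groove that the monomer leaves exposed.
Monomer structure predictors can therefore be co-opted for peptide docking
by presenting the complex as a single chain — receptor sequence, then a
linker of 30 glycines, then the peptide, N- to C-terminus. A predictor that
recognises polyglycine as unstructured will route the linker out of the way
and place the peptide in its site; alternatively the two sequences can be
presented as separate chains. This package implements everything around
that idea except the predictor itself: query construction, model
post-processing, the full metric suite, cohort analytics, and benchmark
curation. The prediction step is an adapter contract (`checkPredictedModel`)
with a deterministic mock implementation used throughout the tests.

Two assumptions run through the design. First, models are built from the
cleaned SEQRES sequence, so residue correspondence between a model and a
native is by SEQRES index, not author numbering; unresolved residues simply
drop out of the pairing. Second, models carry no hydrogens, so "all-atom"
metrics operate on heavy atoms, pairing atoms by name within a residue and
discarding (symmetrically) any atom present on only one side — this is how
a native OXT or a missing side-chain atom is handled.

## Metrics

All superpositions are least-squares rigid fits (Kabsch, SVD with
reflection correction); `backbone` means N, CA, C, O throughout.

* The **interface** is defined on the native only: a residue belongs to it
  iff its Cβ (Cα for glycine) lies within 8.0 Å of any cross-chain Cβ/Cα.
  Defining it on the native keeps a perfect model's interface RMSDs at
  exactly zero; a model-derived set could differ and break that anchor.
* `rmsBB_if`/`rmsALL_if`/`rmsBB_allIF`/`rmsALL_allIF`: superpose the model
  receptor on the native receptor over the backbone atoms of *all* shared
  receptor residues (the FlexPepDock convention, not interface-only), then
  take unfitted RMSDs over the peptide interface residues or over both
  interface sides.
* `Irms` fits on exactly the interface backbone atoms of both sides;
  `Lrms` is the receptor-fitted RMSD over all peptide backbone atoms;
  `Fnat` counts native residue–residue contacts (any heavy-atom pair
  ≤ 5.0 Å, the CAPRI convention) recovered by the model.
* `DockQ = (Fnat + 1/(1+(Irms/1.5)^2) + 1/(1+(Lrms/8.5)^2))/3` with the
  published default constants; it is 1 for a perfect model and tends to
  `Fnat/3` as both RMSDs grow.
* The **binding pocket** uses a backbone-to-backbone 8.0 Å rule on receptor
  residues; pocket recovery is the fraction of native pocket residues also
  in the model pocket. `pocketOccupancy` applies the same rule to an
  arbitrary candidate chain superposed into the receptor frame, which is
  the structural screen for monomers that already carry a peptide-like
  element in the site.
* A model is **failed** when no peptide heavy atom is within 4.0 Å of the
  receptor — the "peptide out in space" mode of linker-based docking. The
  4.0 Å value mirrors the curation contact rule; the failure mode is
  qualitative and any cutoff in this range separates it cleanly.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| interface cutoff | 8.0 | Å | Cβ–Cβ interface rule |
| contact cutoff | 4.0 | Å | curation contact filter, failure flag |
| Fnat cutoff | 5.0 | Å | native-contact definition |
| linker length | 30 | residues | poly-Gly fusion |
| pLDDT cutoff | 0.7 | – | confidence classifier (strict `>`) |
| accuracy cutoff | 2.5 | Å | per-residue "accurate" rule (`<=`) |
| hotspot threshold | 1.5 | kcal/mol | ΔΔG hotspot call (inclusive `>=`) |
| symmetry threshold | 0.20 | fraction | crystal-contact rejection (inclusive) |
| DockQ quality line | 0.6 | – | medium-to-high quality mark |
| best-of-n | 10 | models | merged protocol selection |

`pipelineConfig()` carries these defaults and round-trips through YAML. The
boundary senses are deliberate choices where the protocol's prose shows only
a threshold line: pLDDT strictly above 0.7 (matching "values above 0.7"),
accuracy at ≤ 2.5 Å, hotspots at ≥ 1.5 kcal/mol, symmetry rejection at
≥ 20% ("at least").

pLDDT is normalised to [0, 1] everywhere: predictors emit it in the
B-factor column on a 0–100 scale, so extraction divides by 100 whenever any
raw value exceeds 1.5 (no real confidence sits in (1, 1.5], making the
detection idempotent). Within a residue all atoms must agree to 1e-3,
otherwise the CA value is used with a warning.

## Run-configuration grids

`enumerateGrid()` builds Cartesian products over the six protocol factors
(linkage, recycles, environmental sequences, dropout, seed, parameter set)
in a fixed lexicographic order so that batch manifests are reproducible.
The calibration grid (2×2×2×2×5×5) yields 400 configurations; the merged
default protocol (5 parameter sets × 2 linkages) yields the 10 models per
complex from which best-of-10 selection draws. `bestOfN` minimises a chosen
metric with ties resolved to the lowest model index.

## The synthetic generator

`makeToyComplex` builds a receptor as a bundle of ideal α-helices (rise
1.5 Å/residue, 100° twist, CA radius 2.3 Å, full backbone plus Cβ; 30
residues per helix, 11 Å apart) and a peptide as an extended strand
(3.5 Å/residue) or short helix placed `grooveOffset` Å from the receptor
surface. The construction is self-consistent rather than physical — bond
geometry is approximate, there are no side chains beyond Cβ and no
sterics — which is sufficient because every test compares analyzers against
ground truth recorded by the generator itself with independent brute-force
loops: the interface set, the pocket set, per-residue displacements, and
crystal contact fractions.

`perturbModel` moves the peptide rigidly and adds optional isotropic noise,
so models of exactly known quality exist (a pure translation of norm *d*
yields `rmsBB_if = d`). `makeCrystalFixture` embeds a complex in a P1 cell
whose one axis length is solved — from the exact pairwise contact
intervals — so the neighbouring lattice copy touches exactly
`ceiling(fraction × peptide_len)` peptide residues; the axis is chosen among
a, c, b because threshold spacing depends on the geometry along each
direction, and genuinely unreachable fractions raise an error rather than
approximating. `synthConfidence` maps displacement *d* to `0.7^(d/2.5)`, so
the 2.5 Å accuracy mark coincides exactly with the 0.7 confidence mark and
a noiseless table classifies perfectly; `synthAlascan` draws ΔΔG values
with known hotspot labels around the 1.5 kcal/mol line.

What the fixtures do **not** emulate: real side-chain packing, realistic
B-factor/occupancy patterns, non-trivial space groups (fixtures are P1;
the analyzer, however, applies arbitrary fractional operators and is tested
against hand-written operator strings), alternate locations beyond what the
round-trip tests construct, and any sequence–structure relationship.
Passing tests therefore demonstrate correctness of the *measurement*
machinery, not docking accuracy on real complexes — reproducing published
benchmark accuracy requires running an actual predictor on PDB-derived sets,
which is out of scope here.

## Numerical choices and degenerate inputs

* Kabsch requires ≥ 3 points and a covariance of rank ≥ 2; collinear sets
  and count mismatches are errors. Rotations are proper to 1e-8.
* Altloc handling keeps the highest-occupancy conformer, ties broken
  alphabetically; only the first NMR model is read.
* SEQRES index assignment matches resolved residue numbers to SEQRES codes
  under the best constant offset (models built from SEQRES need no gapped
  alignment); with no SEQRES, numbering relative to the first resolved
  residue is used.
* Sequence cleaning removes UNK anywhere, drops non-standard residues at
  the termini (read as terminal modifications, e.g. ACE/NH2 caps), and maps
  internal non-standard residues through a fixed parent table (MSE→M,
  SEP→S, ...), removing unmapped ones with a message.
* An empty native interface leaves the interface metrics `NA` with a
  warning rather than erroring, so cohort tables keep their shape; an empty
  native pocket is an error for recovery/occupancy (the quantity is
  undefined).
* Spearman correlations use average ranks on ties. Success-curve
  thresholds are inclusive (`<=`).
* Symmetry mates are generated from all operators × lattice translations in
  {−1,0,1}³, skipping the identity image; ±1 cells suffice for 4 Å contact
  detection in cells at least as large as the molecule.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
receptors of 31–40 residues, peptides of 4–25, cohorts of 5–12 complexes
with 10 models each, 100-fixture brute-force comparisons, and
2000-residue confidence tables — sizes chosen so the whole suite exercises
every code path in a few minutes on one CPU while keeping Monte-Carlo
checks inside comfortable estimator bands.

## Known limitations

* Separate-chain queries record linkage abstractly; the chain-break
  mechanism (residue-index offset vs. true multimer input) is left to the
  predictor adapter.
* The mmCIF reader targets the categories the package writes (atom_site,
  cell, symmetry strings, poly_seq_scheme); exotic archival files may carry
  variants it does not parse.
* Whether linker residues should ever be scored is answered here by
  construction: they are discarded at the split and never evaluated.
* `Lrms` fixes backbone as N, CA, C, O; conventions that exclude O will
  differ slightly.
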