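Package: PepDockBench
Title: Evaluation Harness for Peptide-Protein Complex Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A predictor-agnostic harness for benchmarking peptide-protein
    complex models produced by monomer structure-prediction networks. Builds
    fused poly-glycine linker queries, separate-chain queries and poly-alanine
    controls; splits fused models back into receptor and peptide chains and
    flags models whose peptide points out into space; computes the structural
    evaluation suite (FlexPepDock-style interface RMSDs, CAPRI Irms/Lrms/Fnat,
    DockQ, per-residue RMSD, binding-pocket recovery, per-chain RMSD); analyses
    per-residue pLDDT confidence (accuracy classification, motif calling) and
    alanine-scanning hotspot recovery; and curates non-redundant benchmark sets
    with length, contact, UNK, crystal-symmetry-contact and domain-family
    deduplication filters. A synthetic fixture generator provides toy
    receptor-peptide complexes with analytically known geometry so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
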