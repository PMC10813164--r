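Package: ditps3d
Title: Sequence-Structure-Product Analysis of Plant Diterpene Synthases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint sequence, structure, and product-chemistry analysis
    of plant diterpene synthases (diTPS). Provides readers for curated enzyme
    annotation tables, FASTA sequences, and PDB structures with docked substrate
    poses; class I/II signature-motif scanning (DDXXD, DXDD, NSE/DTE, LHS, PNV,
    PIX, FEHXW, FERLW) and domain splitting; pairwise sequence identity matrices
    and sequence similarity networks; substrate-shell extraction ("byres within
    r" selection), Kabsch superposition and TM-score structural alignment of
    shells and whole structures; sequence-order-independent multi-site alignment
    of binding sites, conserved 3D motif extraction with coverage/tightness
    gates, and relaxed 3D motif search; ECFP (Morgan radius-2) fingerprints with
    Dice product similarity and carbon-skeleton reduction; residue composition,
    substrate-shell residue preference, Pearson cross-factor correlation reports
    and same-versus-different group comparisons; plus a deterministic synthetic
    cohort generator with planted ground truth and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ChemmineR,
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
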