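Package: hotsig
Title: Somatic Mutation Hotspots, Activation Signatures, and Protein
    Decay Kinetics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cataloguing somatic mutations from multi-caller
    call sets, detecting per-residue mutation hotspots by Monte-Carlo
    permutation with Benjamini-Hochberg correction, deriving
    gene-expression activation signatures by sequential Ward clustering
    under a machine-learning score, stratifying tumor cohorts into
    normal/active/inactive groups, analysing single-nucleotide codon
    substitution spectra, and estimating protein half-lives from
    cycloheximide chase series. Includes a seeded synthetic-cohort
    generator producing TCGA-like mutation tables, negative-binomial
    RNA-seq count matrices and noisy decay series for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
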