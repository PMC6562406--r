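Package: histonePTM
Title: Quantification of Histone H3 Post-Translational Modifications from
    LC-MS with a Super-SILAC Spike-In
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for relative quantification of combinatorial
    histone H3 lysine methylation and acetylation from bottom-up LC-MS data.
    Models the D6-acetic-anhydride derivatized, Arg-C-like digested histone H3
    substrate (peptide families 3-8, 9-17, 18-26, 27-40 and 73-83), enumerates
    combinatorial peptidoforms with exact monoisotopic masses for light and
    Arg-10 heavy (super-SILAC spike-in) channels, extracts and integrates ion
    chromatograms from centroided MS1 peak lists with valley-based resolution of
    co-eluting isobaric forms, computes percent relative abundance and
    light/heavy ratios, aggregates combinatorial forms into single-residue
    "total mark" scores (e.g. total H3K14ac), and provides the downstream group
    statistics: Student's t tests, Ki-67 correlation, PCA with an explicit
    missing-value policy, correlation-distance average-linkage clustering and
    Benjamini-Hochberg FDR. A synthetic-cohort generator with known ground truth
    makes every stage testable without raw data, and a curated histone-modifying
    enzyme catalogue supports writer/eraser consistency reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mzR,
    jsonlite
Config/testthat/edition: 3
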