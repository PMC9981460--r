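Package: dilac
Title: Detection and Deconvolution of Metabolic Subpopulations by
    Differential Isotope Labelling of Amino Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects metabolic producer/consumer subpopulations from the
    labelling states of peptides carrying multiple copies of one amino
    acid, and deconvolutes the subpopulations' proteomes from bulk
    heavy/light precursor pairs. Provides a carbon-13 isotope mass model
    for peptides and fragments under arbitrary per-residue labelling, in
    silico protein digestion and candidate-peptide selection, fragment
    specific labelling-state quantification from targeted transition
    reports, a binomial homogeneity model with a mixed-state depletion
    statistic, precursor-pair deconvolution of data-independent
    acquisition reports with gene-level hit calling, in silico spectral
    library relabelling, and a seeded population simulator that emits the
    same report formats so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
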