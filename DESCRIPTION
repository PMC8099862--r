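Package: phosphoDIA
Title: Phosphosite Localization, Hybrid Spectral Libraries and Site-Level
    Quantification for DIA Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for data-independent acquisition (DIA)
    phosphoproteomics. Computes peptide, precursor and fragment-ion
    monoisotopic masses with phospho and other variable modifications;
    enumerates positional phospho-isomers, finds site-determining fragment
    ions and scores localization probabilities with a cumulative-binomial
    model; assembles and filters hybrid DDA+DIA spectral libraries with
    segmented iRT calibration; rolls precursor areas up to phosphosite and
    protein abundances; benchmarks dilution series (linearity, ratio
    accuracy, CV, missing-value profiles); performs S0-moderated two-sample
    t-tests with permutation FDR and Fisher's-exact kinase-motif enrichment;
    and simulates spike-in benchmark data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
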