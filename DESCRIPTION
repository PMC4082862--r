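Package: spcregress
Title: Spectral-Count Proteomics Pipeline for Two-Group Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free spectral-count analysis for two-group (e.g.
    regression versus persistence of premalignant lesions) proteomic
    biomarker studies. Implements multistep peptide-spectrum-match
    filtering (charge-dependent Xcorr gates, peptide length,
    consecutive fragment-ion runs, per-sample occurrence, group
    presence), spectral-count offsetting and normalization, PLS-DA
    reduced to a single target-projection component with signed
    selectivity ratios, a discriminating-variable (DIVA) test that maps
    a correct-classification-rate objective to a selectivity-ratio
    significance limit, nested double cross-validation for component
    selection, ROC-derived decision stumps, a two-node classification
    tree, single-variable logistic ranking, and seeded synthetic-data
    generators that emulate the study design for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, pROC, rpart, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
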