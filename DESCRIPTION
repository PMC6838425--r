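Package: ecohab
Title: Ecological Habitat Scoring of Tumour Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quadrat-based ecological analysis of classified cell
    coordinates from tumour tissue sections. Grid squares containing
    cancer cells are labelled as one of four habitats by the relative
    abundance of stromal cells ("resource") and lymphocytes ("hazard");
    habitat counts are combined into a local EcoScore, and Getis-Ord
    hotspot detection yields a distance-ratio global EcoScore. Includes
    cohort dichotomization, a Bonferroni-corrected optimal-cutpoint
    survival search, resource-stratified prognosis of genomic measures,
    grid-shift and square-size robustness sweeps, and a marked
    point-process cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
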