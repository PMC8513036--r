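Package: agpglyco
Title: Serum AGP N-Glycan Isomer Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for alpha-1-acid glycoprotein (AGP) N-glycan
    isomer profiles measured by negative-mode HILIC-MS/MS. Provides a
    composition grammar and monoisotopic mass engine for anthranilic
    acid-labeled N-glycans, Domon-Costello fragment enumeration with
    diagnostic ions for sialic acid linkage (alpha-2,3 vs alpha-2,6) and
    fucose position (core vs antenna), relative-abundance feature
    construction from peak-area tables, Fisher-criterion feature ranking,
    two-class linear discriminant classification with repeated
    leave-one-third-out cross-validation, and a synthetic cohort and
    spectrum generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
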