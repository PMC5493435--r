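Package: crescentr
Title: Quantification of Cortical Polarity Crescents in Asymmetrically
    Dividing Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying cortical polarity crescents in
    asymmetrically dividing epithelial cells such as Drosophila sensory
    organ precursors. Extracts cortical intensity profiles from
    fluorescence images along closed cell outlines, computes circular
    harmonic polarity statistics (the polarization coefficient P and the
    nematic order parameter S), daughter-cell segregation ratios, signed
    division angles relative to the anterior-posterior axis, and crescent
    enrichment ratios. Group comparisons use an exact/approximate
    Mann-Whitney test and the Freeman-Halton extension of Fisher's exact
    test for r x c defect-category tables, both implemented from first
    principles. A synthetic-data generator produces cell images with von
    Mises shaped crescents, division-event populations with wrapped-normal
    angles, and multinomial defect tables, so every analysis stage is
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
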