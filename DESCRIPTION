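Package: tlbkit
Title: Thermal Liquid Biopsy Thermogram Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differential scanning calorimetry (DSC) thermograms of
    blood plasma ("thermal liquid biopsy"): buffer subtraction, protein
    concentration normalization, linear baseline correction and regridding to
    the standard 45-90 degree Celsius analysis grid; extraction of a panel of
    19 thermogram metrics (peak amplitudes and temperatures, valley, amplitude
    ratios, first-moment temperature, width at half height, area);
    non-parametric group comparison with multiple-testing adjustment;
    longitudinal difference profiles; unsupervised k-means clustering of full
    profiles with cluster-purity assessment; and a seeded synthetic-cohort
    generator emulating myocardial-injury phenotype signatures for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
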