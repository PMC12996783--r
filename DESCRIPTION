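Package: retquant
Title: Longitudinal Drusen Morphometry, RPE Outer-Segment Clearance, and
    Lipid Composition Reporting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification pipeline for retinal degeneration studies:
    computes drusen heights from segmented OCT boundary surfaces
    (RPE/photoreceptor-outer-segment and Choroid/Bruch's-membrane boundaries)
    with flanking-section baseline correction, links drusen across imaging
    visits and reports count series, average height changes and per-druse
    change ratios with the field's degenerate-case rules; quantifies
    photoreceptor outer-segment clearance by the RPE as diameter-filtered
    rhodopsin-positive dots per RPE cell over randomly sampled flat-mount
    fields; and summarises phospholipid class composition, binomial phenotype
    frequencies with margins of error, and two-/multi-group tests. Seeded
    synthetic generators for OCT boundary volumes, RPE flat mounts and lipid
    panels make every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
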