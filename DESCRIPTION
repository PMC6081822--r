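Package: octapair
Title: Paired Comparison of Spectral-Domain and Swept-Source OCT/OCTA Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing spectral-domain (SD) and swept-source (SS)
    optical coherence tomography (OCT) and OCT angiography (OCTA)
    acquisitions of the same eyes: total-signal normalization of 3-D scans,
    per-layer signal strength and inter-device signal-strength differences,
    subretinal fluid (central serous) volumetry from layer boundary
    surfaces, registered en-face vessel-density measurement with foveal
    avascular zone exclusion, and a statistical layer of paired t-tests,
    ordinary least-squares regression, and Bland-Altman agreement analysis.
    Includes a synthetic paired-cohort generator with analytically known
    ground truth (half-ellipsoid serous detachments, seeded vascular
    patterns, device-specific sensitivity roll-off) so that every stage of
    the analysis can be validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
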