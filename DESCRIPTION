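Package: stereotau
Title: Design-Based Stereology and Spatial Quantification of Tau
    Pathology in Cortical Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Optical-fractionator population estimates, Gundersen-Jensen
    coefficients of error, Cavalieri volumes and volume-adjusted densities
    for tau-immunoreactive structures (neuropil threads, neuritic thread
    clusters, neurons) annotated on serial cortical sections; spatial
    analyses of the annotation coordinates (cortical-layer assignment,
    sulcal versus gyral partition by the bottom-third-of-sulcus rule,
    perivascular association of markers with blood vessels, and binned
    density heatmaps); and a synthetic annotation-set generator with known
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
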