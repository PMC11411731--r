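Package: hosplink
Title: Longitudinal Record Linkage of Hospital Site Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links annual cohorts of hospital sites across years by a
    similarity-matrix method combining an administrative-code sub-score
    (institution identification code and site code) with a mutual
    nearest-neighbour location sub-score, applies threshold- and
    municipality-based linking decisions with a manual-review queue for
    tied scores, classifies longitudinal continuity (constant, changed,
    opened, closed, with division/merge flags), chains pairwise linkages
    into a multi-year panel with stable identifiers, and evaluates
    linkage quality against gold-standard pairs (true, false and missed
    matches) relative to a code-only baseline. Includes a synthetic
    facility-panel generator with ground-truth linkage so the entire
    pipeline can be exercised without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    igraph,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
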