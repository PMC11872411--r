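Package: cgps
Title: B-Cell Based Discovery and Monitoring of Chronic Graft-Versus-Host Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: A tested pipeline for B-cell based monitoring of chronic
    graft-versus-host disease (cGVHD) after allogeneic stem-cell
    transplantation. From single-cell cytometry matrices it discovers a
    disease-associated B-cell subpopulation by graph-based clustering,
    selects a minimal marker panel by exhaustive combinatorial
    random-forest screening with freeze-then-validate two-cohort
    evaluation, gates the CD27+CD86+CD20- subset among CD19+ B cells,
    maps its frequency to the 0-100 cGVHD Progress Score (cGPS), and
    derives ROC/Youden decision thresholds with bootstrap confidence
    intervals and contingency evaluation. Includes a synthetic cytometry
    cohort generator with a planted plasmablast-like disease subset so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang (>= 1.0.0),
    ggplot2,
    generics,
    readr,
    ranger,
    mclust,
    igraph,
    BiocNeighbors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    uwot,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
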