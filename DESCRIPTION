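Package: granulink
Title: Linking Neutrophil Cytokine Secretion to Degranulation by Linear
    Fitting of Short Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Relates short time series of LPS-stimulated neutrophil cytokine
    secretion to time series of granule-specific degranulation markers.
    Relative ratio profiles (stimulated over time-matched control) are log10
    normalized and every cytokine-marker pair is fitted by ordinary least
    squares; pairs with a significant overall F test and a high adjusted
    R-squared are declared pattern matches and grouped into per-marker
    clusters, with slope-normalized overlay series for plotting. The adjusted
    R-squared acceptance threshold is calibrated by a Monte-Carlo perturbation
    simulation (uniform noise of increasing amplitude applied to each profile,
    averaged over repetitions) followed by exact one-dimensional k-means
    clustering of the average-RSQ-versus-amplitude curve, with silhouette
    analysis to confirm the number of clusters. Includes bundled relative
    secretion and degranulation ratio tables as fixtures, a synthetic profile
    generator for validation, readers and writers for profile tables and
    linkage reports, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
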