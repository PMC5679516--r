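Package: lekshed
Title: Protected-Area Effectiveness Analysis for Sage-Grouse Lek Collapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess how well protected-area polygons ("Core Areas")
    conserve greater sage-grouse, built around annual maximum male lek counts.
    Implements a sliding-window lek-collapse statistic (zero males in three
    consecutive surveyed years), conjugate beta-binomial posterior estimates of
    annual collapse probability by spatial stratum with credible intervals,
    signed boundary-distance stratification of leks relative to Core Area
    boundaries, lagged oil and gas well densities in buffer rings outside the
    boundaries, pairwise edge-effect regressions of collapse probability on
    adjacent development density, and a logit-link prediction of percent change
    in Core Area lek attendance. A synthetic landscape generator (disjoint core
    polygons, clustered well fields, overdispersed cyclic lek counts with a
    latent activity chain, and a collapse-rate calibration routine) emulates the
    restricted state monitoring databases so the whole pipeline is testable and
    reproducible end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
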