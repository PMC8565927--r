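Package: scable
Title: Passive Cable Modeling and Synapse Mapping for Cerebellar Stellate Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Tools for studying electrotonic filtering of quantal synaptic
    signals in thin-dendrite interneurons. Provides SWC morphology input and
    output, idealized stellate-cell construction and morphometrics (Sholl
    analysis, branch statistics, FWHM diameter estimation), analytic cable
    constants, a passive compartmental solver for branched trees under voltage
    and current clamp, simulation protocols (quantal EPSC distance sweeps,
    paired-pulse ratio, subthreshold input-output curves, dendritic
    sublinearity, synapse-distribution-weighted mean miniature EPSC
    synthesis), a puncta-to-skeleton synapse mapping pipeline with distance
    histograms and distribution statistics, kinetic analysis of synaptic
    current traces, and synthetic-data generators with known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
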