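Package: hemolag
Title: Trial-Based Hemolysis Modelling for Continuous-Flow Ventricular
    Assist Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts pump-induced hemolysis in continuous-flow left
    ventricular assist devices (LVADs) without computational fluid
    dynamics.  A modified power-law model of the hemolysis rate index
    (HRI), identified from in vitro hemolysis trials, is made dynamic
    through a one-dimensional Lagrangian particle scheme over the
    impeller region and coupled to pump speed/hydraulic dynamics and a
    lumped-parameter model of the assisted cardiovascular system.
    Includes robust power-law fitting of trial data, hydraulic model
    identification, cardiac-cycle-synchronised speed-modulation
    profiles, operating-mode sweeps, and seeded synthetic-data
    generators for trials, blood-sample series and hydraulic bench
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
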