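Package: mogflow
Title: Metric-Optimised Gating and Flow Quantification for Fetal
    Phase-Contrast Cine MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Retrospective cardiac synchronisation of ungated, oversampled
    segmented phase-contrast cine MR by entropy minimisation over
    hypothetical two-interval heart-rate triggers (metric-optimised gating),
    together with a pulsatile-vessel k-space acquisition simulator,
    through-plane flow quantification, fetal shunt accounting (combined
    ventricular output, pulmonary blood flow, foramen ovale flow), and
    Bland-Altman / regression agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
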