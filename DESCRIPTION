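Package: tiptempo
Title: Temporal Signal and Best-Fitting Roots for Heterochronous Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Regression of root-to-tip genetic distance against tip sampling
    time to quantify temporal signal in heterochronous sequence data,
    exact best-fitting-root search by residual minimization (or root-to-tip
    distance variance for isochronous trees), and residual / ancestor-trace
    diagnostics for detecting sequences whose divergence and sampling date
    are incongruent. Includes tip-date parsing (decimal years, ISO dates,
    label extraction, tab-delimited tables) and a clock-tree simulator with
    known ground truth and injectable anomalies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
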