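Package: icresp
Title: Intermittent-Closed Respirometry and Whole-Animal Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing intermittent-closed (intermittent-flow)
    respirometry of fishes and the energetic metrics built on it: dissolved-oxygen
    trace handling, closed-phase slope extraction with background correction,
    quantile-based standard metabolic rate, steepest-sliding-window maximum
    metabolic rate, aerobic scope, Q10 thermal sensitivity, residual-based
    allometric adjustment of metabolic rates and somatic indices, and
    body-composition, growth and protein-synthesis metrics. Includes a
    physics-based simulator of respirometer oxygen dynamics and fish metabolic
    state (acute thermal scaling, gradual cold compensation, starvation
    depression, spontaneous activity bouts) so every estimator can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
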