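Package: dsrt
Title: Dual-Readout Drug Sensitivity and Resistance Testing Analytics
Version: 0.1.0
Authors@R: person("DSRT", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-dose, multi-compound drug screens
    read out with paired cell-viability and cytotoxicity channels. Provides
    plate normalization to percent inhibition / percent toxicity with
    Z'-factor quality control, four-parameter logistic dose-response fitting
    (bottom fixed at zero), closed-form drug sensitivity scores (DSS) and
    selective DSS against a reference panel, cytostatic-versus-cytotoxic
    response classification, Bliss independence and zero-interaction-potency
    (ZIP) scoring of 8x8 dose-combination matrices, anchored combination
    screens with delta-DSS flagging, complete-linkage clustering of response
    profiles with TreeView-compatible export, and responder-group protein
    marker association. A synthetic screen generator with known ground truth
    emulates the 384-well experimental design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
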