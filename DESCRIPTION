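Package: aepbk
Title: PBK Modelling and Reverse Dosimetry (QIVIVE) for Aloe-Emodin and
    Its Metabolite Rhein
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Physiologically based kinetic (PBK) modelling and quantitative
    in-vitro-to-in-vivo extrapolation (QIVIVE) for the natural
    hydroxyanthraquinone aloe-emodin and its active metabolite rhein, in
    rats and humans.  The package fits Michaelis-Menten parameters and
    intrinsic clearance from in-vitro incubation data and scales them to
    whole-liver values, integrates a two-compound flow-limited PBK model
    (oral and intravenous routes), translates in-vitro
    concentration-response curves into predicted in-vivo dose-response
    curves by reverse dosimetry with relative-potency weighting of the
    metabolite, derives benchmark-dose points of departure (BMDL10/BMDU10)
    with bootstrap confidence bounds, and compares them against estimated
    daily intakes from food supplements and herbal medicines.  A
    synthetic-data module generates every dataset shape the pipeline
    consumes, with known ground truth, so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
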