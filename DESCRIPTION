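Package: cirtconvert
Title: Fractionation and RBE-Model Conversion of Carbon-Ion Radiotherapy
    Dose Constraints
Version: 0.1.0
Authors@R:
    person("cirtconvert", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for converting organ-at-risk dose constraints in
    carbon-ion radiotherapy (CIRT) between fractionation schemes with the
    linear-quadratic (LQ) iso-effect model and between relative biological
    effectiveness (RBE) models -- the microdosimetric kinetic model (MKM)
    and the local effect model (LEM) -- via a monotone anchor-interpolated
    dose-conversion curve.  Implements the two strategy orderings used to
    derive hypofractionated rectum constraints for prostate CIRT (LQ first
    in MKM space, or RBE conversion first then LQ in LEM space), cumulative
    dose-volume-histogram (DVH) metrics D_x% and D_xcc with constraint
    compliance evaluation for patient cohorts, seeded synthetic DVH and
    cohort generators, and command-line reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
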