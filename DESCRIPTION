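Package: capnosv
Title: Capnodynamic Mixed Venous Oxygen Saturation Estimation and
    Method Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Breath-by-breath estimation of mixed venous oxygen
    saturation (SvO2) from volumetric capnography via the differential
    Fick principle: effective pulmonary blood flow (EPBF) is fitted from
    a cyclic ventilation pattern (six normal breaths followed by three
    breaths with an expiratory pause), oxygen consumption is derived
    from CO2 elimination and a fixed respiratory quotient, and venous
    oxygen content is inverted through the oxygen-hemoglobin
    dissociation curve.  Includes the method-comparison statistics used
    to validate such monitors (inherent precision, least significant
    change, Bland-Altman analysis corrected for repeated measurements,
    four-quadrant concordance with an exclusion zone) and a synthetic
    porcine endotoxemia experiment generator (LPS induction followed by
    fluid, oxygen, PEEP, inotrope, vasopressor, hemorrhage and
    retransfusion challenges) producing hemodynamic ground truth,
    breath streams and three noisy SvO2 recording modalities, so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
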