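Package: ringplan
Title: Multi-Field IMRT Planning Toolkit for Ring-Gantry Breast and Nodal
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and evaluating multi-field intensity-modulated
    radiotherapy (IMRT) of the whole breast or chest wall with regional lymph
    nodes on ring-gantry (Halcyon/Ethos-class) machines. Provides automated
    15-17 field beam-angle placement from a chosen medial tangent, planning
    target volume construction by Euclidean margin morphology (expansion, skin
    pullback, planning-risk-volume cropping, conformity rings, virtual bolus
    shells), cumulative dose-volume histogram metrics (VxGy, DxCC, mean,
    near-maximum), piecewise-linear dosimetric scorecards with color bands,
    gamma-index patient-specific quality assurance (3 percent / 2 mm with a
    10 percent low-dose threshold), exact Wilcoxon rank-sum plan comparison,
    and a parametric thorax phantom with a simplified ray-cast dose engine so
    the full pipeline runs end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
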