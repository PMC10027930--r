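Package: meropbpk
Title: Whole-Body PBPK and Dose Evaluation of Meropenem in Chronic Kidney
    Disease and Hemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A whole-body, perfusion-limited physiologically based
    pharmacokinetic (PBPK) model of meropenem with a mechanistic kidney
    submodel (glomerular filtration, OAT3 basolateral uptake, NPT1 apical
    efflux, intracellular DPEP1 metabolism), scaled to chronic kidney
    disease stages 3-5 under the intact nephron hypothesis and extended
    with an intermittent-hemodialysis dialyzer clearance model. Includes
    virtual-population generation, non-compartmental analysis, model
    qualification metrics (MRD, GMFE, two-fold classification), local
    sensitivity analysis, seeded Monte-Carlo parameter calibration, and
    Monte-Carlo probability-of-target-attainment (PTA) evaluation of
    dosing regimens at fT>MIC pharmacodynamic targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
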