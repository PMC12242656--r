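Package: dyseep
Title: Dynamic Simulations for Evaluation of Economic Potential of Batch
    Bioprocesses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples dynamic flux balance analysis (DFBA) of batch
    fermentations to a techno-economic model so that alternative bioprocess
    scenarios can be ranked by monthly gross profit and assessed with full
    project economics (ROI, payback, NPV, IRR).  Reads constraint-based
    metabolic models in BiGG-style JSON or SBML (level 3, FBC), augments them
    with a poly-3-hydroxybutyrate (PHB) synthesis pathway (NADPH- or
    NADH-dependent acetoacetyl-CoA reductase) and glucose transport, solves
    the embedded flux balance analysis linear programs with a built-in
    bounded-variable simplex, integrates the batch mass balances with a stiff
    adaptive integrator, scans growth-associated flux trade-offs and
    two-phase glucose allocations, and compares flux variability analysis
    envelopes between scenarios to suggest genetic interventions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
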