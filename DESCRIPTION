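Package: lqrepurpose
Title: Drug Repurposing by Linear-Quadratic Control of Signed Gene Networks
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models a disease's signed gene-interaction network as a
    discrete-time linear dynamical system, computes the optimal
    linear-quadratic-regulator (LQR) intervention that would stabilize a
    dysregulated expression signature back to equilibrium, and scores real
    drugs by how well their quantified target-mechanism vectors match that
    optimal intervention. Includes discretization of differential-expression
    top-tables into {-1, 0, +1} disease signatures, a fixed-point solver for
    the discrete algebraic Riccati equation, therapeutic scoring with
    ROC/AUC evaluation of approved-versus-withdrawn drug sets, a synthetic
    scenario generator with planted ground truth, and a command-line
    interface over the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
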