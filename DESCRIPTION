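Package: crannav
Title: Navigated Craniosynostosis Surgery Analysis Pipeline
Version: 0.1.0
Authors@R: person("crannav", "developers", role = c("aut", "cre"),
    email = "crannav@example.org")
Description: Computational core of a surgical-navigation workflow for
    craniosynostosis correction: two-step rigid fiducial registration
    (primary on surgical-guide points, repeatable secondary on bone pins)
    with fiducial RMSE bookkeeping under head motion, navigation-accuracy
    evaluation against an intraoperative surface scan via exact
    point-to-triangle-mesh distances, craniometric outcome metrics
    (interfrontal angle, transverse forehead width), Laplacian mesh
    smoothing and hole filling, and a synthetic skull-phantom generator
    that exercises the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
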