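Package: hingescope
Title: Hinge-Bending Domain Motion Analysis for Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of hinge-bending domain motions in two-domain enzymes
    such as angiotensin-converting enzyme (ACE) from molecular-dynamics
    trajectories and crystal structures. Computes the lip-center distance
    across the active-site cleft, classifies frames into closed, semi-open
    and open conformational states, measures the interdomain hinge-bending
    angle by subdomain-anchored two-stage rigid superposition (Kabsch),
    and provides Calpha RMSD/RMSF trajectory statistics and geometric
    hydrogen-bond detection and counting. Includes a synthetic two-domain
    hinge-trajectory generator with exact ground truth (angle schedule,
    state sequence, planted hydrogen bonds) so every analysis stage can be
    validated without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
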