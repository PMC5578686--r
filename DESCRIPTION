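Package: msclrod
Title: Rod-and-Connector Mechanics of MscL Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained structural mechanics of the bacterial
    mechanosensitive channel of large conductance (MscL). Implements a
    pentameric rod-and-connector model in which the four helices of each
    subunit are elastic rods and the hydrophobic pore-lock is a network of
    25 pairwise van der Waals connectors described by generalized
    Lennard-Jones force laws. Provides seeded synthetic generators for
    interaction energy/force curves, helix stress-strain and load-unload
    traces, and idealized closed/open pentamer geometries; nonlinear
    displacement-controlled static solving of gating scenarios; pore
    diameter and TM1 stress metrics; and an encoding of eleven in-silico
    pulling scenarios covering interaction-strength reduction, belt
    deletion, and the G22N gain-of-function variant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
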