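Package: chirodeb
Title: Dynamic Energy Budget Life-Cycle Model for the Harlequin Fly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Full life-cycle bioenergetic simulation of the non-biting midge
    Chironomus riparius under variable food and temperature, built on Dynamic
    Energy Budget (DEB) theory. Implements a 'hax'-type model for
    holometabolous insects with metabolic acceleration during the first three
    larval instars, biphasic growth in the fourth instar, and a dual trigger
    for pupation (reproduction-buffer density followed by reserve density).
    Provides stage-structured ODE integration with event detection, Arrhenius
    temperature correction with an upper tolerance boundary, Holling type II
    food forcing, observables (physical length, wet and dry weight, fecundity,
    survival), a synthetic-data generator, and multi-dataset parameter
    estimation by Nelder-Mead minimisation of a symmetric bounded loss with
    pseudo-data support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
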