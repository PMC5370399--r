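Package: nephrokin
Title: Mechanistic Kidney Model for Renal Drug Disposition of Digoxin
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Physiologically based simulation of renal drug disposition for
    digoxin. Implements a compartmental nephron model (glomerulus plus seven
    tubular segments with filtrate, cell and blood exchange) with passive
    diffusion, OATP4C1-mediated basolateral uptake and saturable P-gp apical
    efflux, coupled to a reduced two-compartment systemic model. Provides
    Cockcroft-Gault renal-function arithmetic, in vitro-in vivo extrapolation
    helpers, virtual-population sampling for healthy, geriatric and
    renal-impairment groups, sensitivity-analysis and profile-fitting
    estimation of transporter intrinsic clearance, and scenario engines for
    renal-impairment mechanism sweeps.
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
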