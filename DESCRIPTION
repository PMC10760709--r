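Package: walkopt
Title: Energy-Optimal Walking Speeds for Short Bouts and Turning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the preferred walking speed of lower-limb prosthesis
    users as the minimiser of a metabolic cost: a quadratic steady-rate
    cost per unit body mass, a start-stop term proportional to the
    kinetic-energy change scaled by muscle work efficiencies, and a
    turning cost proportional to the squared angular rate.  Provides
    forward prediction of optimal speeds for straight bouts of given
    distance and circles of given radius, inverse optimization of the
    changing-speed and turning cost coefficients from observed trial
    speeds with fine-grid validation, a paired one-sided bootstrap
    hypothesis battery with Bonferroni correction, fixed-effects linear
    speed-distance and speed-radius fits, and a synthetic cohort
    generator that emulates the trial design (five straight distances,
    three circle radii walked in both directions) for fully reproducible
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
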