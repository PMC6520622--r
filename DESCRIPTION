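Package: heftr
Title: Grip Kinetics and Heaviness Perception for Precision-Grip Lifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how people lift and perceive bipartite
    objects (objects whose two halves look like different materials).
    Provides a physics-based generator of synthetic two-digit precision-grip
    lifts recorded by dual six-axis force/torque sensors, the signal
    processing pipeline that extracts grip force, load force, digit centers
    of pressure, net object torque and movement-phase events from such
    recordings, perceptual-rating transforms and illusion indices for
    material-weight-illusion designs, the associated statistical battery
    (mixed/repeated-measures ANOVA with Greenhouse-Geisser correction,
    t-tests, Bonferroni adjustment, JZS Bayes factors), and a Bayesian
    competing-priors observer that predicts the direction of weight
    illusions under different judgment tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
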