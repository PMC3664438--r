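Package: smcagent
Title: Sensorimotor Contingency Analysis for a Minimal Categorical
    Perception Agent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a minimal model of active categorical perception: a
    one-dimensional agent with a derivative-sensing continuous-time recurrent
    neural network (CTRNN) controller, evolved to approach narrow and avoid
    wide bell-shaped gradients on a circular track.  Provides the four
    operational sensorimotor-contingency analyses for such coupled
    agent-environment systems: the open-loop sensorimotor environment
    (sensory change over position and commanded velocity, with its symmetries
    and extrema), the closed-loop sensorimotor habitat (trajectory ensembles
    and quasi-static fixed-point, bifurcation and attractor-landscape
    analysis), sensorimotor coordination (limit-cycle detection in
    sensorimotor rate space tied to task function), and a verdict slot for
    sensorimotor strategies.  Includes a real-valued genetic algorithm over
    controller parameters, a frozen reference evolved agent, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
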