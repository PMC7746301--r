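Package: loopstate
Title: Structural and Bifurcation Analysis of a Positive-Feedback-Loop Model of ALS Pathogenesis
Version: 1.0.0
Authors@R:
    person("loopstate", "maintainers", email = "loopstate@example.org", role = c("aut", "cre"))
Description: Implements a six-variable ordinary-differential-equation model of
    motor-neuron energy metabolism in amyotrophic lateral sclerosis (ALS),
    in which mutant SOD1 perturbs mitochondrial oxidative phosphorylation and
    three overlapping positive feedback loops couple AMPK, PFK3, APC-Cdh1,
    the pentose phosphate pathway and glutamate excitotoxicity.  Provides
    parameter-free structural analysis of the signed interaction graph
    (interaction and input sign matrices, feedback-loop census, candidate
    multistationarity, monotone gauge detection, structural influence
    matrices via the sign of the adjoint of the negative Jacobian), numerical
    equilibrium finding with stability and health classification, knockout
    analysis with a closed-form steady state, bifurcation sweeps over the
    strength of the PFK3-to-PPP inhibition with fold detection and hysteresis
    runs, and a seeded random-parameterization generator that searches for
    bistable regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
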