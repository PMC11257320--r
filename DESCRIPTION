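Package: bilatOR
Title: Homogeneity Tests of the Odds Ratio for Stratified Bilateral and
    Unilateral Binary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Likelihood-ratio, score, and Wald tests of whether the odds
    ratio comparing two treatment groups is constant across strata when
    each subject contributes either correlated bilateral responses from
    paired organs (intraclass-correlation model of Donner) or a single
    unilateral response.  Includes the constrained and unconstrained
    maximum-likelihood algorithms (closed-form cubic root for the event
    probabilities combined with Fisher scoring and Newton-Raphson),
    Monte-Carlo facilities for empirical type-I-error and power studies,
    two worked clinical datasets (acute otitis media, orthokeratology for
    myopia), and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
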