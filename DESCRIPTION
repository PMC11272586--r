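Package: effortmap
Title: Effort-Discounting Choice Models and Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling prosocial effort-based decision making and
    relating behaviour to focal brain damage. Implements a twelve-model space
    of effort-discounted subjective value (linear, hyperbolic and parabolic
    cost functions with shared or recipient-specific discounting and choice
    consistency parameters), softmax choice simulation on a balanced factorial
    grip-force task schedule, hierarchical maximum a posteriori fitting by
    expectation maximization with integrated BIC and pseudo-R2, random-effects
    Bayesian model selection (estimated model frequencies and exceedance
    probabilities), simulation-based model identifiability and parameter
    recovery studies, behavioural payoff and grip-force metrics, and a native
    voxel-based lesion-symptom mapping routine with permutation-based
    threshold-free cluster enhancement inference. Synthetic cohort generators
    for choices, force traces and lesion masks allow the full pipeline to run
    end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
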