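Package: normtraj
Title: Bayesian Developmental Trajectories of Sharing Norms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian logistic developmental-trajectory models to binary
    sharing choices from a two-condition Dictator Game run in two societies.
    A shared infant sharing probability and four society-by-condition logistic
    acquisition curves (with gender offsets) are estimated by adaptive
    Markov chain Monte Carlo under Beta and truncated multivariate-normal
    priors. Derived statistics include norm-acquisition completion ages,
    inter- versus intra-ethnic completion-age contrasts with a posterior
    hypothesis-support rule, gender-marginalized sharing rates, and a
    simulation-based power study. Companion tools cover participant-exclusion
    accounting, a synthetic study generator that emulates the experimental
    design, and free-list interview analysis (frequency, Smith's salience,
    and learning-mechanism tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
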