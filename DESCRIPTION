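Package: epigain
Title: Bayesian Information-Gain Models of Epistemic-Emotion Valence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical models of epistemic-emotion valence as Bayesian
    information gain under the free-energy principle. Computes the two
    information gains of a one-dimensional Gaussian generative model --
    recognition gain (the Kullback-Leibler divergence of prior from
    posterior) and Bayesian surprise -- both in closed form and under a
    likelihood augmented with a uniform noise floor, which turns the gains
    into inverted-U ("Wundt curve") functions of prediction error and
    surprise. Provides bounded-scalar optimisation of the gain curves,
    variance sweeps over prior and likelihood uncertainty, predictive
    free-energy decompositions (expected recognition gain, mutual
    information, ambiguity, risk), and a deterministic simulator of
    alternating diversive/specific curiosity cycles. Results are tibbles
    with ggplot2 autoplot(), broom-style tidy()/glance() methods, and a
    command-line interface for CSV/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
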