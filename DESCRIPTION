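Package: srtrace
Title: Trial-by-Trial Successor Representation Learning from Graph-Walk Reaction Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people learn multi-step predictive
    representations from sequences of stimuli drawn from random walks on
    graphs. Simulates serial reaction time experiments on modular, lattice
    and random 15-node graphs; implements recency, one-step, SR-TD(lambda)
    (with dutch eligibility traces) and static successor-representation
    learners; fits them to reaction times with a hierarchical shifted
    log-normal likelihood via expectation maximization with Laplace-
    approximated marginal likelihoods; compares models with AIC-penalized
    scores and paired t-tests; and runs model-agnostic trace and bootstrap
    sequence-signature analyses together with the novel-cluster-entry
    contrast.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    igraph,
    pracma,
    lme4,
    lmerTest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
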