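Package: eventdep
Title: Retrieval Dependency Analysis for Three-Element Event Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing holistic retrieval in episodic memory
    experiments in which each "event" comprises three elements (for
    example an animal, an object and a location) and every pairwise
    association is tested in both directions by four-alternative forced
    choice. Implements the retrieval dependency statistic, which compares
    the observed proportion of jointly correct or jointly incorrect
    retrieval trials, averaged over the six contingency tables that share
    a common cue or a common target, against an independent model built
    from participant-level marginal accuracies. Provides long-format
    trial data input and output with missing-response scoring and
    ceiling/floor participant exclusion, one-sample and Welch t tests
    with Cohen's d, Jeffreys-Zellner-Siow Bayes factors with a Cauchy
    prior on the standardized effect and prior-robustness sweeps, exact
    noncentral-t power analysis, and a seeded synthetic-data generator
    implementing a latent mixture of holistic (all-or-none, event-level)
    and independent (trial-level) retrieval with forced-choice guessing
    and counterbalanced trial schedules.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
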