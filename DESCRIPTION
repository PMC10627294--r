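Package: dmsdt
Title: Signal Detection Analysis of Pattern Perception in Binary Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how observers discriminate patterned from
    random binary token sequences in a signal detection task. Generates
    random, Markov, and disrupted-Markov stimulus sequences and balanced
    experimental sessions; computes the full Bayesian ideal observer via a
    two-state forward recursion over the hidden Markov chain, with exact
    (complete enumeration) and Monte Carlo performance; extracts four
    candidate pattern features (longest run, longest alternation, repetition
    count, color predominance) and builds ideal single-feature classifiers
    from their exact distributions; fits logistic feature-combination models
    with fully standardized (Menard) coefficients; compares all feature
    subsets by small-sample corrected AIC (AICc) and evidence ratios; and
    estimates equal-variance Gaussian sensitivity (d'), criterion, and
    efficiency relative to the ideal observer. Includes a synthetic-observer
    simulator (noisy weighted-feature rule with lapses) so the entire
    fitting pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
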