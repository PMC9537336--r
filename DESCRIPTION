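Package: weam
Title: Weighted Entropic Associative Memory for Phonetic Representation and Learning
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Weighted associative memory registers (AMRs): n x m tables of
    non-negative integer weights storing discrete feature functions, with
    additive registration, relaxed-implication recognition and stochastic
    constructive retrieval. Provides Shannon-entropy measures of register
    indeterminacy, an ensemble memory system with an entropy-weighted
    Bayesian class decision, min-max quantization of real-valued feature
    vectors, phone-string evaluation tools for the Mexbet-22 Mexican
    Spanish alphabet (tokenizer, token Levenshtein distance, phoneme error
    rate, bigram-based string simplification), an incremental self-training
    loop with corpus balancing, and a synthetic class-conditional data
    generator so that every component is testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
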