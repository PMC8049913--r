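Package: ensemblebias
Title: Matched-Pair Bias Estimators, JZS Bayes Factors and Design Analysis
    for Group-Ensemble Memory Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for matched-pair continuous-report
    experiments on ensemble-statistics bias in visual working memory:
    a synthetic trial-level experiment generator, three per-participant
    bias estimators (difference score, ratio of averages, averaging
    ratios) with Monte-Carlo type-I-error analysis of their t-tests,
    the JZS default Bayes factor for the one-sample t-test with a
    zero-centered Cauchy prior, a Gibbs sampler for the JZS posterior of
    the mean, classical power analysis and fixed-n Bayes Factor Design
    Analysis (Monte-Carlo and analytic engines), and the pre-planned
    replication analysis pipeline (accuracy-versus-chance test, bias
    t-test, Bayesian t-test, posterior credible interval, sanity-subset
    rerun).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
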