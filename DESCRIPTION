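Package: abxtalk
Title: Mining Social-Media Discussions of Antibiotic Ineffectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for infodemiology studies of
    patient-reported antibiotic ineffectiveness on French-language forums and
    microblogs. Implements lexicon-based corpus inclusion (antibiotic keyword
    conjoined with an inefficiency lexical field in the same message) and an
    auditable exclusion cascade; scored gender prediction and two-stage age
    inference (regular expressions with a gradient-boosted model fallback);
    a from-scratch biterm topic model with collapsed Gibbs sampling,
    single-topic document assignment and cross-topic characteristic-token
    extraction; a two-stage quality-of-life impact classifier (binary gate
    plus five per-domain gradient-boosted models); and summary-table
    aggregation of sources, monthly volume with a November-March seasonality
    index, topic shares, cohort demographics and impact prevalences. A
    synthetic-corpus generator with full latent ground truth makes every
    stage testable without collecting any real user data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    stringi,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
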