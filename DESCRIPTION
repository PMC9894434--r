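Package: veracue
Title: Verbal Veracity Cues from Dependency-Parsed Statements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for lexicon- and syntax-based analysis of
    truthful versus deceptive statements. Reads dependency-parsed corpora in
    CoNLL-U format together with a statement manifest and category lexicons,
    and computes a battery of psycholinguistic features per statement:
    syntactic complexity via mean dependency distance (MDD) and mean
    hierarchical distance (MHD), readability via the Gunning Fog index,
    Linguistic Category Model (LCM) abstraction scores, lexicon-based
    sentiment, negation and over-generalization rates, detailed
    part-of-speech counts, and length measures. Features are compared between
    conditions with sum-contrast random-intercept linear mixed models fitted
    by profiled REML with Holm-corrected Wald tests, and fed to a
    cross-validated truth/lie classifier. A synthetic-corpus generator with
    configurable, recorded ground-truth effects makes every stage testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    e1071,
    xgboost,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
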