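Package: q53match
Title: Patient Similarity Matching for the Q53 Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: k-nearest-neighbor matching of questionnaire respondents under 24
    distance and similarity measures drawn from eight mathematical families
    (Minkowski, L1, intersection, inner product, fidelity/squared-chord,
    squared L2, Shannon entropy, combined), with a leave-one-out "matching
    accordance" evaluation harness against a pseudorandom-matching benchmark,
    paired permutation significance tests, a 2D t-SNE cohort embedding, and a
    synthetic cohort generator emulating a 973-respondent rare-disease study
    population. Cohorts are flat CSV tables of demographics, diagnostic
    metadata and 53 ordinal answers coded 1-5.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
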