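Package: umni
Title: Unmet Medical Need Index Scoring, Rater Agreement, and Factor Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying relative unmet medical need across
    diseases. Scores each disease on eleven criteria spanning patient
    suffering, standard of care, and accessibility using a 1-5 rubric,
    combines criterion scores into a weighted composite with ranking and
    percentile presentation, reconciles and compares independent raters
    (expert or language-model based) with disagreement tabulation,
    performance gates, Spearman/bootstrap and Wilcoxon statistics, and
    characterizes the latent structure of score matrices with Bartlett,
    Kaiser-Meyer-Olkin, parallel-analysis, and maximum-likelihood factor
    analysis diagnostics. Ships seeded synthetic-data generators so the
    full pipeline runs offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
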