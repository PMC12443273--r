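Package: ncdlisten
Title: Social-Media Listening Toolkit for Non-Communicable Disease Comment Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, testable pipeline for mining public social-media
    comments about non-communicable diseases (NCDs). Parses saved HTML
    comment sections via CSS-selector configurations, cleans and anonymizes
    bilingual (Thai/English) comment tables, extracts dashboard variables by
    lexicon matching, classifies comments into a three-category taxonomy
    (sharing experience, inquiring, non-informative) with class-imbalance
    oversampling, builds retrieval-augmented summaries behind a pluggable
    text-generation backend, aggregates results into a user-validated
    dashboard data model, and ships the accompanying evaluation-statistics
    toolkit: Likert-scale interpretation, Mann-Whitney U tests with mean
    ranks and tie correction, and a-priori power analysis for two-sample
    t tests via the noncentral t distribution. Seeded synthetic-data
    generators reproduce every input the pipeline consumes so that all
    stages are testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    rvest,
    yaml,
    jsonlite,
    readr,
    tibble,
    dplyr,
    stringi,
    Matrix,
    glmnet,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
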