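Package: postopsat
Title: Postoperative Patient-Satisfaction Scoring and Five-Year Survey Trend Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hospital patient-satisfaction questionnaires
    from surgical wards. Implements a composite multiplicative satisfaction
    index built from demographic (gender, age, residence), medical (infection,
    complication, care protocol, innovative products) and pain factors, with a
    three-band interpretation (high/moderate/low satisfaction); quality-control
    exclusion of questionnaires with more than 20 percent missing responses;
    ward-by-year Likert summaries with one-way ANOVA and Tukey HSD post hoc
    tests; paired year-pair t tests reconstructable from printed summary
    statistics; Shapiro-Wilk-gated Spearman rank correlation; Cronbach's alpha;
    and a calibrated synthetic questionnaire-cohort generator emulating an
    8-ward by 5-year study design so the whole pipeline is testable without
    patient-level data.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
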