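Package: emopheno
Title: Person-Centered Subgrouping of Emotion-Processing Deficits in Conduct Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates case-control cohorts of youths with conduct disorder and
    typically developing controls, including trial-level logs for three
    neuropsychological tasks (facial emotion recognition on morphed-expression
    continua, passive avoidance learning, and an emotional go/nogo task), and
    re-runs the full person-centered analysis on them: regression adjustment of
    task scores for age, IQ and sex; a confirmatory three-component principal
    component analysis with varimax rotation and Anderson-Rubin factor scores;
    age-bracketed normative 10th-percentile deficit classification against the
    control distribution; multi-deficit (Venn) overlap analytics; dimensional
    mixed-design ANOVA and logistic group discrimination; and association tests
    between deficit flags and clinical scales (YPI callous-unemotional traits,
    reactive/proactive aggression) and risk factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
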