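Package: microguild
Title: Guild-Based Longitudinal Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal (repeated-measures) microbiome
    cohorts at the level of co-abundance guilds: within-subject co-abundance
    correlation, Ward clustering with sequential permutational-MANOVA tree
    cutting to delineate guilds, subject-stratified PERMANOVA, covariate
    (subject)-adjusted principal coordinates analysis, a normality-gated
    repeated-measures screening cascade (one-way repeated-measures ANOVA,
    Friedman/Nemenyi, Dunnett-versus-baseline, Benjamini-Hochberg), guild to
    metabolite association via a random-intercept model on arcsine
    square-root transformed abundances, and a seeded synthetic-cohort
    generator with planted guild structure for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    cluster
Config/testthat/edition: 3
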