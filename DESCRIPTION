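Package: pigrowth
Title: Logistic Growth Inflection Analysis and Post-Inflection Trait
    Screening for Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits logistic growth curves to longitudinal pig body-weight
    records and derives the growth inflection point, maximum daily gain and
    the maximum-deceleration ("optimal slaughter") age in closed form.
    Models post-inflection trait trajectories (e.g. loin muscle area and
    intramuscular fat versus body weight) with quadratic and asymptotic
    families and detects plateau weights; screens carcass, meat-quality and
    composition traits for weight-dependent trends via one-way ANOVA with
    Tukey HSD, correlation matrices, hierarchical clustering and PCA; and
    quantifies relative gene expression from qPCR cycle thresholds by the
    2^-ddCt method. A synthetic two-breed herd generator reproduces the
    statistical structure of lean-type and fat-type fattening data so the
    whole pipeline is testable without animal records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
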