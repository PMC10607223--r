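Package: pkpgx
Title: Pharmacokinetic and Pharmacogenetic Association Analysis for
    Antihypertensive Crossover Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental pharmacokinetic (NCA) estimation from
    concentration-time profiles (trapezoidal AUC, terminal-slope
    extrapolation, dose- and dose/weight-normalised exposure), star-allele
    genotype-to-phenotype translation (CYP2D6 activity score, transporter
    function classes), and the candidate-gene association cascade used in
    crossover bioequivalence cohorts: Shapiro-Wilk normality gating with log
    fallback, univariate t/ANOVA or rank tests with Bonferroni post hoc,
    multivariate linear regression of screened predictors, paired
    pharmacodynamic tests and exact contingency-table tests for adverse drug
    reaction incidence. A synthetic-cohort generator emulates the demographic,
    genotypic and sampling structure of seven valsartan, olmesartan and
    hydrochlorothiazide trials so that every stage is testable end to end
    without access to sponsor-held data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
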