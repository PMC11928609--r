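Package: mrpath
Title: Two-Sample Mendelian Randomization with Metabolite Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Two-sample summary-data Mendelian randomization for
    drug-target analyses: cis-eQTL instrument selection (significance,
    F-statistic, cis window, MAF, palindrome and LD-clump filters with a
    full exclusion provenance log), allele harmonization, a univariable
    estimator suite (Wald ratio, fixed- and random-effects IVW, MR-Egger,
    weighted median, simple and weighted mode), sensitivity diagnostics
    (Cochran's Q and I-squared, Egger intercept, MR-PRESSO global and
    outlier tests, leave-one-out, funnel export), two-step mediation with
    delta-method confidence intervals for the proportion mediated,
    multivariable IVW adjustment, and a ground-truth summary-statistics
    simulator of the exposure-mediator-outcome chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
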