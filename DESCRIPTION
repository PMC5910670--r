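Package: chemmap
Title: Positional Chemical-Modification Analysis and Design for siRNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screening-paradigm statistics for chemically modified small interfering
    RNA (siRNA) duplexes combining 2'-deoxy-2'-fluoro (2'-F) and 2'-O-methyl (2'-OMe)
    ribosugar modifications. Provides a notation and domain types for modified strands,
    synthetic generators for in vitro silencing screens and in vivo
    pharmacokinetic/pharmacodynamic time courses with planted ground truth, the
    positional multiple-linear-regression model of per-position 2'-F versus 2'-OMe
    effects on silencing, covariate-adjusted design-variant comparison from
    delta-delta-Ct quantification, constrained search for minimal-2'-F modification
    patterns, and an in vivo analysis suite (semilog EC50/EC80 fits of Argonaute-2
    loading versus knockdown, extra-sum-of-squares F-tests, baseline-referenced AUC,
    recovery-slope comparison, and two-way ANOVA with Dunnett and Sidak post-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
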