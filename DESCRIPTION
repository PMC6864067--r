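Package: assortMR
Title: Disentangling Assortative Mating with Cross-Spouse Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to distinguish assortative mating from social homogamy,
    partner interaction effects and relationship dissolution as explanations
    of spousal concordance on a heritable behaviour such as alcohol
    consumption. Provides a couple simulator implementing the four
    concordance mechanisms over a geographically structured population, a
    household-based spouse-pair derivation pipeline with per-step exclusion
    ledger (including LD pruning and genomic-relatedness filtering),
    cross-spouse Mendelian randomization estimators (Wald ratio,
    fixed-effects IVW with Cochran's Q and I-squared, MR-Egger, weighted
    median and weighted mode), spousal phenotypic, genotypic and
    polygenic-score concordance regressions, population-stratification
    diagnostics (Hardy-Weinberg tests, allele-frequency comparisons,
    SNP-geography associations, within-centre fixed-effects meta-analysis,
    birth-distance stratification), and closed-form expected cross-spouse
    correlations under single-round phenotypic assortment.
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
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
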