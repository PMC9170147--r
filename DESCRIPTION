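Package: gamecap
Title: Quantitative Genetics of Doubled-Haploid and Gamete-Capture
    Populations Derived from Landraces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genome-enabled prebreeding
    of allogamous crop landraces.  Simulates an ancestral landrace in
    Hardy-Weinberg equilibrium with within-chromosome linkage
    disequilibrium, derives doubled-haploid (pure) and gamete-capture
    (admixed) populations by simulated meiosis, doubling and selfing, and
    evaluates them with closed-form quantitative-genetic expectations of
    population means and additive variances, molecular diversity
    statistics (polymorphism census, genetic distances, AMOVA, LD decay,
    linkage-phase similarity), multi-environment trial analysis with REML
    variance components and entry-mean heritability, and GBLUP genomic
    prediction with the full set of cross-validation scenarios (within and
    across populations, across landraces, combined training sets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    minpack.lm,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
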