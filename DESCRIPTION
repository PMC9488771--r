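Package: duckhybrids
Title: Attribution of Wild Duck Hybrids to Parental Species, Mothers, and
    Siring Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hybridization in broadly sympatric ducks from
    reduced-representation genotypes, mitochondrial haplotypes, and
    breeding-season abundance maps. Implements read-count genotype scoring and
    locus/individual filtering for ddRAD panels, supervised ancestry
    estimation against parental reference allele frequencies with F1 and
    backcross classification, maternal species assignment from mtDNA by
    nearest reference distance, an abundance-overlap resampling null model for
    expected hybrid-pair frequencies with standardized effect sizes, and exact
    binomial and Fisher tests for siring asymmetries. A synthetic-data
    generator reproduces the statistical structure of every input so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
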