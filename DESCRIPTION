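Package: crosstrait
Title: Cross-Trait Proxy-Phenotype Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for cross-trait statistical genetics with GWAS summary
    statistics: harmonization and quality control of association results,
    linkage-disequilibrium utilities (pairwise r2, greedy clumping, proxy
    search, LD scores), the proxy-phenotype lookup with raw and
    MAF-matched enrichment tests, winner's-curse correction and Bayesian
    credibility of candidate loci, a minimal LD-score regression for
    heritability and genetic correlation, an LD-aware enrichment test,
    genome-wide inferred statistics (GWIS) trait purging, polygenic score
    construction with sign-concordance splits and a nested-model F test
    for genetic heterogeneity, and a synthetic-data generator that
    emulates the full study design (LD-blocked genotypes, mixture genetic
    architectures, liability-threshold case-control ascertainment, and a
    deeply phenotyped patient cohort).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
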