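Package: ketonet
Title: Co-Expression Modules, Trait Association and GWAS Signal Enrichment for
    Bovine Ketosis Transcriptomics
Version: 0.1.0
Authors@R:
    person("Ketonet", "Developers", email = "ketonet@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline linking blood-leukocyte gene co-expression
    modules to metabolic disease status and blood bio-indicators, and to GWAS
    signal enrichment. Builds weighted gene co-expression networks (soft
    thresholding, topological overlap, hierarchical module detection, module
    eigengenes), associates module eigengenes with physiological states and
    bio-indicators, scores modules for enrichment of GWAS summary statistics
    with a sum-of-squared-effects statistic and a circular genotype
    permutation null, scores tissue-specific expression with a +1/-1
    regression t-statistic, and extracts candidate genes. Ships a synthetic
    data generator with planted modules, trait couplings and locally inflated
    SNP effects so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
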