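Package: snpcc
Title: Candidate-Gene Case-Control SNP Association, Haplotype, Epistasis
    and Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complete analysis pipeline for small candidate-gene
    case-control SNP panels: Hardy-Weinberg equilibrium testing, allelic
    and genotypic odds-ratio association with Woolf confidence intervals
    and Fisher exact fallback, EM estimation of haplotype frequencies
    from unphased genotypes, pairwise linkage disequilibrium (D, D', r2),
    exhaustive multifactor dimensionality reduction (MDR) search for
    gene-gene interactions with cross-validation consistency, permutation
    significance and entropy-based interaction maps, and Kaplan-Meier
    survival with log-rank tests by genotype. Includes a seeded
    synthetic-cohort generator (block-LD genotypes, penetrance-table
    disease models including pure two-locus epistasis, missingness,
    right-censored survival) so every stage can be validated against
    known ground truth, plus readers for PLINK PED/MAP and CSV genotype
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
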