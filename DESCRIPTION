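Package: pedimpute
Title: Simulation and Evaluation of Genotype Imputation Strategies in Large Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation framework for assessing genotype-imputation study
    designs in extended pedigrees. Generates founder haplotype pools with a
    controllable minor-allele-frequency spectrum and distance-decaying linkage
    disequilibrium, drops haplotypes through pedigrees with recombination to
    obtain phased truth genotypes, selects reference-panel subjects under four
    strategies (random, maximally unrelated, generation units, founder
    coverage), imputes masked genotypes with transparent family- and
    population-style baselines or imports results from external tools via VCF,
    scores per-SNP accuracy (dosage R-squared, imputation quality score,
    concordance), and estimates type-I error and power of mixed-model
    association tests per minor-allele-frequency bin.
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
    withr
Config/testthat/edition: 3
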