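Package: mcld
Title: Monte Carlo Test of Linkage Disequilibrium from Unphased SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Testing linkage disequilibrium (LD) between two bi-allelic SNPs
    from unphased population genotype data. Haplotype frequencies are estimated
    by a two-locus EM algorithm and summarized as D, D' and r-squared; the test
    statistic N*r^2 is referred to a bootstrap null distribution obtained by
    independently resampling single-locus genotypes and re-pairing them, which
    keeps the type-I error rate correct despite the extra variability that
    haplotype-frequency estimation introduces (a naive chi-square reference
    grossly inflates it). Includes simulators for two-SNP genotype data under
    Hardy-Weinberg equilibrium or disequilibrium and under a given level of
    gametic disequilibrium, and study drivers that measure type-I error and
    power of the test at configurable scale. Reads genotypes from VCF or a
    plain 0/1/2 dosage matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
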