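Package: rohsel
Title: Runs of Homozygosity, LD-Based Effective Population Size and
    Long-Range Haplotype Selection Scans for Bottlenecked Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genomic analysis of small, strongly
    bottlenecked diploid populations genotyped on SNP arrays. Reads and
    writes PLINK text and binary genotype files, applies per-SNP call-rate,
    autosome and minor-allele-frequency filters, detects runs of
    homozygosity (ROH) with an exact run-based scan and a derived
    false-positive-controlled SNP-count threshold, pools consensus ROHs,
    and computes the genomic inbreeding coefficients F_ROH and F_IS
    together with pedigree-based F with generation truncation. Estimates
    the historical effective population size trajectory from
    distance-binned linkage disequilibrium via the Sved relation, and
    scans phased haplotypes for recent positive selection with the
    extended haplotype homozygosity (EHH) and relative EHH (REHH)
    long-range haplotype test. A forward-in-time Wright-Fisher simulator
    with recombination, mutation, admixture and additive selection
    generates phased genotypes, true pedigrees and known demography for
    validation. All analysis results are returned as tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
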