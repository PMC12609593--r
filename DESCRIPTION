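Package: rdnactive
Title: Absolute and Presumably Active Ribosomal DNA Copy Number in Sperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies absolute ribosomal DNA (rDNA) copy number per haploid
    genome from droplet digital PCR (ddPCR) droplet counts via Poisson
    occupancy statistics, and the "presumably active" copy number from deep
    bisulfite sequencing (DBS) of the rDNA promoter amplicon: per-read CpG
    methylation calling, bisulfite conversion-rate and allele filtering,
    10-percent methylation binning, and the product of absolute copy number
    with the hypomethylated (<= 10 percent) read fraction. Includes a cohort
    statistics layer (Mann-Whitney U with tie-corrected asymptotics and exact
    enumeration, Spearman correlations, normality checks, logistic regression
    on pregnancy outcome, minimum-copy-number analysis), a WHO 5th-edition
    semen-parameter classifier, and a synthetic-cohort generator (droplet
    tables, bisulfite FASTQ reads, sample sheets) so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
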