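Package: rohdiv
Title: Runs of Homozygosity, Genomic Diversity and Effective Population
    Size from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide diversity analysis for SNP-array genotypes of a
    single population, as applied in canine conservation genetics. Reads
    and writes PLINK text (PED/MAP) and binary (BED/BIM/FAM) genotype
    files, applies array quality-control filters (autosomes, call rate,
    minor allele frequency, individual missingness), computes per-locus
    and mean observed/expected heterozygosity, F_IS and per-individual
    molecular inbreeding, detects runs of homozygosity (ROH) with a fully
    parameterised sliding-window caller including the Lencz minimum-SNP
    threshold, derives F_ROH against the SNP-covered autosome length,
    summarises ROH incidence and islands, prunes loci by variance
    inflation factor, and estimates contemporary effective population
    size from linkage disequilibrium with small-sample bias correction.
    A seeded genotype simulator with plantable homozygous tracts and a
    Wright-Fisher drift model makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
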