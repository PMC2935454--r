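Package: meleagris
Title: Hybrid-Platform Draft Genome Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for downstream analysis of draft genomes assembled from a
    mixture of long-read pyrosequencing and short-read sequencing data, in the
    style of the early avian genome projects. Implements tiered heterozygous
    single-nucleotide-variant (SNV) classification from read pileups with
    quality-sum and homopolymer filters, platform-exclusive coverage
    partitioning with Poisson coverage expectations, scaffold-to-chromosome
    anchoring from merged marker maps with misjoin splitting and AGP export,
    lineage acceleration tests on dN/dS tables (differentially evolved genes
    with Benjamini-Hochberg FDR control, paired lineage assignment, rank-sum
    group comparisons, GO-term dissimilarity clustering), and gene-family
    copy-number rate analysis. A seeded synthetic-data module generates
    diploid pileups, marker scenarios, omega tables and copy-number matrices
    with known planted truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
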