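Package: poolHI
Title: Hybrid-Index Genome Scans and Backcross Simulation for Pool-Seq
    Introgression Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing experimental introgression between two
    Drosophila species via pooled sequencing of backcross females. Provides a
    forward-in-time simulator of the F1 -> BC1 -> BC2 crossing design with
    ancestry tracts, a single obligate crossover per female meiosis (50 cM
    map), crossover suppression inside chromosomal inversions in
    heterokaryotypic mothers, and an optional dominant incompatibility locus;
    exact two-locus enumeration of allele frequencies under a
    dominant-recessive Bateson-Dobzhansky-Muller incompatibility; a pool-seq
    hybrid-index pipeline (site filters, diagnostic SNPs, per-SNP hybrid
    index with orientation flipping, chromosome summaries, SNP windows);
    fertility and SNP-density tests; simulation-based quantile envelopes for
    chromosome-wise mean hybrid index; and a synthetic-data generator with
    known truth so the whole pipeline runs without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
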