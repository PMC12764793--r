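Package: haplobin
Title: Haplotype-Specific K-Mer Binning and Phasing Evaluation for
    Heterozygous Diploid Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational stages of a reference-based haplotype-resolved
    assembly workflow for highly heterozygous diploid genomes: haplotype
    consensus construction from phased variants, canonical k-mer counting
    and haplotype-specific k-mer extraction, three-way binning of long
    reads or unitigs, evidence-based purging of redundant allelic contigs,
    phasing-quality statistics (window non-reference allele ratios,
    phase-switch-rate estimation, phase-block statistics, phasing
    discordance) and between-haplome sequence-variation categorization
    from extended CIGAR alignments. Includes a synthetic diploid genome
    and long-read simulator with full ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    igraph,
    vcfR,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
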