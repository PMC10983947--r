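Package: mucvntr
Title: Haplotype-Resolved Analysis of Protein-Coding VNTRs in Secreted Mucins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise protein-coding variable number tandem
    repeat (VNTR) loci such as the secreted airway mucins MUC5AC and MUC5B
    from phased haplotype assemblies. Projects a reference gene model onto
    haplotype sequences via exon-flank anchors and predicts proteins;
    segments predictions into cysteine-rich and tandem-repeat domains by
    template scanning and classifies protein groups; decomposes degenerate
    VNTR segments into consensus-period motifs by wraparound dynamic
    programming, builds motif catalogues, allele strings, normalised usage
    matrices, UPGMA clusterings and position frequency matrices; and runs
    population-genetic scans (Tajima's D in genomic bins with empirical
    percentile flags, D-prime confidence intervals and Gabriel haplotype
    blocks, Hardy-Weinberg and contingency chi-square tests, and
    haplogroup-tagging SNP discovery by squared correlation). A synthetic
    cohort module generates haplogroup-structured VNTR haplotypes and
    coalescent SNP panels under neutral, star and balanced genealogies for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    Biostrings,
    vcfR,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
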