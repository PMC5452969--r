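Package: mitoprofile
Title: Human Mitochondrial Genome Profiling from High-Throughput Sequencing Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles human mitochondrial genome alignments (BAM/SAM) mapped to a
    single mtDNA reference: quality-filtered pileup construction and alignment
    summary statistics, consensus assembly under majority, best-score and
    combined base-calling rules, heteroplasmy detection by minor allele
    frequency, haplogroup assignment from PhyloTree-style defining variants
    with a contamination indicator, ancient-DNA deamination damage profiling,
    consensus-versus-reference variant calling via a built-in global pairwise
    aligner, CSV-based variant annotation, and a static HTML quality report.
    Includes a single-end read simulator with known truth (error rate,
    contamination fraction, terminal deamination) so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
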