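Package: exoprobe
Title: Explorative Degenerate Probe Design for Functional Gene Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and in-silico evaluation of explorative degenerate
    oligonucleotide probes for functional DNA microarrays. From a protein
    multiple alignment the package backtranslates each column into a
    degenerate (IUPAC + inosine) codon, concatenates the codons into a
    nucleic consensus, enumerates candidate probes under degeneracy and
    inosine-content thresholds, expands them into fully specified probe
    sets, screens them for cross-hybridization against a CDS-plus-flank
    background database using Kane's empirical specificity criteria (75
    percent identity, 15-base identical stretch) with rescue of hits that
    belong to the targeted gene family, and normalizes functional
    microarray intensities into a spatially segmented signal-to-noise
    statistic (SNR') with replicate-median positive calls. Deterministic
    simulators for homologous protein families, decoy-planted background
    databases and spotted arrays make every stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
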