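Package: tascan
Title: Screening and Conservation Analysis of Chromosomal Type I
    Toxin-Antitoxin Loci
Version: 0.1.0
Authors@R:
    person("The tascan authors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Detects chromosomal type I toxin-antitoxin loci in bacterial
    genome assemblies with a seed-and-extend local nucleotide aligner
    (Karlin-Altschul bit scores and E-values), classifies loci as full,
    interrupted, antitoxin-only or toxin-only and tallies copy number in
    0.5-copy units, quantifies conservation of regulatory elements and
    toxin open reading frames (consensus matrices, information content,
    protein variant tables), scores antitoxin-to-toxin base-pairing
    repression potential, and tests copy-number differences across
    metadata groups with Monte Carlo ANOVA and Tukey procedures. Includes
    a synthetic pan-genome simulator with planted ground truth so the
    whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
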