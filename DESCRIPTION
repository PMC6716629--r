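Package: bimotif
Title: Bipartite DNA Motif Discovery by Entropy Minimization with
    Mononucleotide and Dinucleotide Weight Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ab initio discovery of bipartite (two-block, variable-gap)
    transcription factor binding motifs in DNA sequence sets. A Gibbs-style
    search with random multi-restart initialization and greedy per-sequence
    placement updates minimizes the Shannon relative entropy of the
    concatenated motif under either a mononucleotide position weight matrix
    (PWM) or a dinucleotide weight matrix (DWM) that captures
    nearest-neighbour base interdependencies. Supports one-occurrence,
    zero-or-one-occurrence and any-number-of-repeats site models, site
    scoring by log-odds, nucleotide-level correlation coefficient (nCC)
    evaluation against known sites, pairwise positional mutual information,
    and a synthetic sequence generator with planted bipartite motifs for
    benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
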