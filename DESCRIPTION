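Package: micmac
Title: Germline-Soma Genome Rearrangement Analysis for Ciliates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing programmed DNA elimination and chromosome
    breakage in ciliates with nuclear dimorphism, modelled on the
    Tetrahymena thermophila germline (MIC) / somatic (MAC) genome pair.
    Includes a miniature rearranged-genome simulator with full ground
    truth (chromosome breakage sequences, internal eliminated sequences,
    non-maintained chromosomes, telomere addition), degenerate-motif
    scanning and variant classification for the 15-bp chromosome breakage
    sequence family, conservation and strand-asymmetry statistics,
    deletion-based centromere mapping, Fitch small parsimony for
    cross-species breakage-site variants, duplication-clade detection
    with a randomized-flank null, three alignment-evidence methods for
    internal eliminated sequence detection with junction merging,
    terminal-direct-repeat and excision-variability statistics, and
    MIC-MAC cross-assembly tiling into chromosome-length super-assemblies
    with windowed feature-density tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
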