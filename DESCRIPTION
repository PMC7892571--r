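Package: barcodekit
Title: Codon-Aware Degenerate Primer Design and Barcode-Gap Species
    Delimitation for COI Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mitochondrial COI DNA barcoding workflows in taxa
    with non-standard mitochondrial genetic codes, such as ascidians.
    Implements genetic-code aware degenerate primer design (IUPAC degeneracy
    algebra, codon-level invariance analysis, 3' anchor placement that avoids
    code-specific hazards such as AGR-glycine first positions), in-silico
    primer evaluation with 3'-clamp mismatch rules and amplicon extraction,
    column-wise alignment statistics (sequence-logo information content,
    strict consensus, variable-site counts, haplotype dereplication),
    pairwise p/JC69/K80 distances with pairwise deletion, barcode-gap species
    delimitation over a grid of prior intraspecific divergences with initial
    and recursive partitions, partition concordance analysis, and a seeded
    simulator of codon alignments with planted species clusters for fully
    offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    mclust,
    stats,
    tools,
    utils
Suggests:
    ape,
    BiocGenerics,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
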