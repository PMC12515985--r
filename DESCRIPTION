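Package: mitocub
Title: Mitogenome Composition, Codon Usage Bias and Nucleotide Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for annotated animal mitochondrial genomes:
    base composition with AT/GC strand skews, positional (codon-site)
    composition, relative synonymous codon usage (RSCU) with bias
    classification under the invertebrate mitochondrial genetic code,
    start/stop codon census, parity-rule-2 (PR2) bias plots, neutrality-plot
    (GC12 on GC3) regression with mutation-versus-selection classification,
    and sliding-window nucleotide diversity over multi-species alignments.
    Includes a synthetic mitogenome and star-phylogeny alignment generator
    with analytic ground truth so every stage is testable without external
    data, plus GenBank flat-file and FASTA input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
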