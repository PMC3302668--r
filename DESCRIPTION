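Package: parclip
Title: Interaction Site Calling and Motif Enrichment for PAR-CLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for delineating RNA-binding-protein interaction sites from
    PAR-CLIP short-read data. Aligned reads are grouped, T=>C crosslink
    conversions are separated from other mismatches, and a Gaussian
    kernel-density classifier contrasts conversion against non-conversion
    signal within each read group to call high-resolution interaction sites,
    with fixed-width or read-based site extension. Downstream analyses include
    IUPAC motif scanning, non-redundant microRNA seed-match assignment,
    signal-to-noise estimation against expressed-gene backgrounds,
    evidence-ranked de novo motif discovery, and a seed-restricted miRNA
    enrichment regression with dinucleotide confounders and a permutation
    null. A seeded simulator generates synthetic PAR-CLIP libraries (reference,
    annotation, aligned reads with conversions) so the whole pipeline can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
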