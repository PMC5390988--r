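Package: diverscan
Title: Interspecific Divergence Scanning from Two-Species Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality-filtered SNP calling from per-species samtools text
    pileups mapped to a common reference transcriptome, the interspecific
    differentiation index D = |FRm - FRr| per SNP and its per-transcript
    mean with fixed-difference classification, reciprocal-best-hit ortholog
    detection with protein-guided codon alignment and Nei-Gojobori (1986)
    Ka/Ks estimation including a Ks >= 1 paralog filter, and GO term
    over-representation testing of highly differentiated transcripts with
    Benjamini-Hochberg FDR control.  A synthetic two-species transcriptome
    generator with full ground truth (fixed differences, shared and private
    polymorphisms, per-gene omega, a planted enriched GO term) makes the
    whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
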