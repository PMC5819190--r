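Package: thermopep
Title: Comparative Genome Mining of Fungal Peptidases and Thermostability
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genome mining of peptidases in thermophilic
    and mesophilic fungi. Assigns proteome sequences to MEROPS-style peptidase
    families and catalytic types by k-mer prescreened Smith-Waterman best-hit
    search against an annotated reference library; compares species-level
    peptidase count profiles with from-scratch Bray-Curtis, ANOSIM, SIMPER and
    tie-corrected Kruskal-Wallis permutation statistics; tests amino-acid
    compositional shifts associated with thermal adaptation; screens pepsin-like
    (A1A) aspartic-peptidase homologs for ordered catalytic hallmark motifs; and
    counts interior cavities of protein structures with a probe-augmented voxel
    grid flood fill. A synthetic-data generator with recorded ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
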