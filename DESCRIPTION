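Package: ppmatch
Title: Profile and Pattern Matching for Reliable Enzyme-Function Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a profile-and-pattern matching (PPM) workflow for
    high-confidence identification of enzyme function in poorly annotated
    genomes such as single amplified genomes (SAGs) of extremophiles.
    Translates lists of Enzyme Commission (E.C.) numbers into non-redundant
    Gene Ontology term profiles and PROSITE consensus-pattern lists, filters
    annotated gene collections through independent profile and pattern
    filters plus a gene-fragment reliability filter, groups surviving hits
    into ranked descriptor-combination sets and condenses them into enzyme
    families. Includes a PROSITE consensus-pattern parser and scanner,
    derivation of relaxed consensus patterns from alignments of functional
    residues, and within-family phylogenetic clustering (Poisson-corrected
    distances, neighbor joining) with representative selection for
    downstream expression studies. Seeded simulators generate annotated
    gene collections, planted-motif protein sets and clustered alignments
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    BiocGenerics,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
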