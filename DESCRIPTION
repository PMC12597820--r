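Package: telocharter
Title: Chromosome-End Architecture and Assembly Curation for Telocentric Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the structure of telocentric (mouse-like) genome
    assemblies: terminal canonical telomere array detection, centromeric
    satellite region delineation, subtelomeric repeat-pattern classification,
    similarity plus Hi-C based placement of unplaced satellite contigs,
    reference-gap fill classification against a complete assembly, inversion
    breakpoint repeat-enrichment and non-allelic homologous recombination
    mechanism calling, and an iterative seed-extension ("walking") targeted
    assembler for repetitive loci. Ships a synthetic genome-pair generator with
    a complete ground-truth ledger so every analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
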