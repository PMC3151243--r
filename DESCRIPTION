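Package: introgain
Title: Cartography and Dating of Spliceosomal Intron Gains in Vertebrate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping recently gained spliceosomal introns across
    genes and species: extraction of introns from gene structures (GFF3 or
    plain exon tables), per-intron descriptors (size, GC content, splice
    signals, proto-splice-site compliance, perfect simple repeats, ultrasmall
    flags), projection of insertion points onto a reference protein numbering
    with phase letters, detection of positionally conserved introns across
    genes and taxa, Dollo-parsimony mapping of intron gains onto dated species
    trees, DRY-motif codon-usage analysis for GPCRs, and a seeded synthetic
    data generator that produces gene structures with known ground truth so
    the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    ape,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
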