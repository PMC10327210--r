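Package: rpntools
Title: Discovery and Characterization of Intragenic Toxin-Antitoxin Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for finding and characterizing genes-within-genes of the
    Rpn (recombination-promoting nuclease) toxin-antitoxin family.  Detects
    internal translation initiation sites (iTIS) inside annotated coding
    sequences by combining in-frame start-codon scanning, Shine-Dalgarno
    motif scoring and initiation-trapped ribosome-profiling peak calling;
    designs minimal-change knockouts of an iTIS; quantifies four-amino-acid
    tandem repeat variation across strain homologs; scans elements for
    transposition signatures (terminal inverted repeats, target-site
    duplications, tandem direct duplications); tests defense-gene
    neighborhood enrichment with an exact Mann-Whitney U test; computes
    structural descriptors (solvent-accessible surface area, dimer
    interface buried area, helix-bundle composition); and provides
    deterministic quantification helpers for SEC-MALS stoichiometry,
    efficiency of plaquing and one-step burst size.  Includes seeded
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
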