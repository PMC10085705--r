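Package: permotif
Title: Block-Permuted RNA Motif Descriptors, Scanning, Covariation and
    Cleavage Kinetics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents structured RNA motifs (such as the hammerhead
    ribozyme catalytic core) as permutable blocks of conserved sequence
    and stem half-sites. Enumerates all block permutations, classifies
    each ordering as a helical junction or a pseudoknotted topology by
    counting crossing stem pairs, and scans nucleotide sequences for
    matches to any permutation with exhaustive backtracking over
    degenerate literals, paired stems and variable-length linkers.
    Candidate alignments are screened with mutual-information based
    covariation statistics and plausibility filters, and self-cleavage
    rate constants are estimated from fraction-uncleaved time courses by
    one-phase exponential decay fits. A synthetic-data module generates
    ground-truthed planted-motif sequences, compensatory-mutation
    alignments and noisy decay curves for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, MotifDiscovery, StructuralPrediction
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'kinetics.R'
    'covariation.R'
    'descriptor.R'
    'simulate.R'
    'constructs.R'
    'io.R'
    'permotif-package.R'
    'scanner.R'
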