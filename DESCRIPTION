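Package: sixsanno
Title: Annotation of 6S RNA Loci with Synteny Rescue, Adaptive Terminator
    Calling, cre Motif Scanning and pRNA Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for annotating bacterial 6S RNA (ssrS) loci
    and their regulatory context. Provides seeded ungapped homology search
    with Karlin-Altschul significance, synteny-constrained rescue of weak
    candidates near rarA/uspA anchor genes, redundancy reduction of
    near-identical sequences to representative consensus sequences,
    Rho-independent terminator calling with a shuffled-genome adaptive
    significance threshold (dinucleotide-preserving Eulerian shuffle),
    catabolite-responsive-element (cre) motif scanning with exact p-values
    under a first-order Markov background, and projection of pRNA
    transcription start sites through multiple alignments with motif-guided
    shift correction. A synthetic-cohort generator plants ground-truth loci
    so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
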