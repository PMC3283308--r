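Package: gdd
Title: Genome Dedoubling by DCJ and Reversal
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction of non-duplicated ancestral genomes from genomes
    whose segmental duplications were produced by breakpoint-duplication
    rearrangements. Implements the genome dedoubling model: signed, copy-labelled
    marker genomes with linear and circular chromosomes, breakpoint-duplication
    DCJ and reversal operations, the dedoubled adjacency graph and its
    path/cycle decomposition, maximum independent sets of non-duplicated cycles
    (exact branch-and-bound and a deterministic greedy heuristic), DCJ
    dedoubling distances and scenarios for multichromosomal and linear
    unichromosomal genomes, and reversal dedoubling of oriented linear genomes
    via a dedoubled overlap graph with local complementation. Includes seeded
    simulators of breakpoint-duplication evolution and breadth-first-search
    oracles for validation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
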