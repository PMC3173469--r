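Package: ncycamp
Title: Functional-Gene Amplicon Analysis of Soil Nitrogen-Cycling Communities
Version: 0.1.0
Authors@R:
    person("Field", "Microbiome Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for barcoded amplicon surveys of the
    nitrogen-cycling marker genes nifH, archaeal and bacterial amoA, nosZ and
    16S rRNA. Provides read demultiplexing and quality screening, a translated
    (six-frame, protein-space) search with frame-consistency frameshift and
    multi-origin chimera rules, dereplication and furthest-neighbour OTU
    clustering with analytic rarefaction and depth re-sampling, monotonic
    abundance-trend detection across crop treatments and years, absolute qPCR
    quantification from sample-derived standards, and T-RFLP community
    analysis (in-silico terminal restriction digests, Bray-Curtis, ANOSIM,
    correspondence analysis). Ships a synthetic-community generator that emits
    every input with known ground truth (sample of origin, OTU membership,
    planted chimeras, single-indel frameshifts, planted abundance trends) so
    the whole pipeline is testable without sequencer output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
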