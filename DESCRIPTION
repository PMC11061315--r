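Package: tnpbtools
Title: Discovery and Characterization of RNA-Guided TnpB Nucleases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering RNA-associated nucleases
    in microbial genomes and characterizing a programmable TnpB-family
    endonuclease from sequencing reads. Includes defense-island mining from
    annotated contigs, a structure-constrained RNA motif scanner for
    intergenic regions, two-step protein family clustering (greedy identity
    clustering followed by profile-similarity Markov clustering), taxonomy
    consensus and RNA-protein co-occurrence statistics, plus read-level
    characterization tools: target-adjacent motif (TAM) enrichment logos,
    cut-site and overhang mapping from run-off reads, small-RNA transcript
    anatomy, amplicon indel quantification, guide-mismatch heatmaps and
    off-target candidate enumeration. Ships synthetic-data generators with
    ground truth for every input so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    S4Vectors,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
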