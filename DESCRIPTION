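Package: lspprn
Title: Local Spatial Pattern Alignment Protein Residue Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds superposition-free protein residue networks from
    conformational ensembles by local spatial pattern (LSP) alignment:
    every pair of structures in a time window is compared residue-pair by
    residue-pair through a four-number Calpha/Cbeta orientation descriptor,
    retained links are averaged into edge weights, and weighted degree and
    betweenness centrality profiles (with window-wise standard errors and
    mutant-versus-reference percent differences) identify stable hubs and
    communicator residues. Includes a seeded synthetic-ensemble generator
    with planted rigid blocks and flexible loops, multi-model PDB input,
    and GraphML/GEXF/TSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
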