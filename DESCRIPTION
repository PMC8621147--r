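Package: gliadinr
Title: Annotation and Celiac-Epitope Analysis of Gamma-Gliadin Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing prolamin (gamma-gliadin) gene families
    in wheat genomes: discovery of intronless open reading frames, pseudogene
    classification by premature stop codons arising from C-to-T transitions in
    glutamine codons, segmentation of the deduced proteins into the canonical
    six-domain gamma-gliadin architecture, cysteine skeleton and poly-glutamine
    tract profiling, physicochemical calculations (average molecular weight and
    Bjellqvist isoelectric point), exact-match scanning against a celiac-disease
    epitope database, pairwise identity matrices and neighbor-joining
    phylogenies.  A synthetic-data generator emits gamma-gliadin-like genes and
    loci with fully known ground truth so every stage of the pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
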