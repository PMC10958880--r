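Package: hittriage
Title: Post-Generation Hit Triage for De Novo Molecule Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, testable pipeline for turning large sets of de novo
    generated 3D molecules into a small, diverse, testable hit list:
    structure validation, chemical-physical property filtering (molecular
    weight, AlogP, polar surface area, rotatable bonds), hit calling by
    synthetic accessibility (SAscore), drug-likeness (QED) and a
    forcefield-style binding score with the GBVI/WSA functional form,
    Bemis-Murcko scaffold extraction with maximum-dissimilarity clustering
    of circular fingerprints, Fisher's-exact-test chemotype (SAR)
    enrichment with a dynamic binding-score cutoff sweep, shape +
    pharmacophore Tanimoto-Combo library searching, and a 2-D
    chemical-space overlap map built on t-SNE with buffered-disc geometry.
    A seed-deterministic synthetic-library generator with planted
    enrichment structure makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
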