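Package: pcmcp
Title: Proteochemometric Affinity Models with Conformal Prediction Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for proteochemometric (PCM) modeling of
    protein-ligand binding affinity with calibrated uncertainty. Curates
    ChEMBL-style IC50 activity tables (unit, confidence, comment, duplicate,
    PAINS and molecular-weight filters; median aggregation; pIC50
    conversion), featurizes ligands (4096-bit ECFP6 fingerprints plus eight
    physicochemical descriptors) and proteins (amino-acid, dipeptide and
    composition-transition-distribution sequence descriptors, 567 values),
    builds generic Bemis-Murcko scaffold, random and protein-held-out
    splits, trains random-forest and entity-embedding feed-forward
    neural-network regressors with per-instance uncertainty (tree spread,
    Monte Carlo dropout), and wraps them in inductive conformal regression
    with spread-normalized nonconformity to produce validity- and
    efficiency-evaluated prediction intervals. Ships a synthetic-data
    generator that emulates the statistical structure of public bioactivity
    data so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ChemmineR,
    ChemmineOB,
    ranger,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
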