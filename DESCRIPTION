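Package: protstab
Title: Protein Stability Change Prediction from Language-Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting the effect of single amino-acid
    substitutions on protein stability (ddG, kcal/mol) from sequence
    embeddings. Implements a thermodynamic-dataset curation pipeline with
    pH/temperature-aware aggregation, conflict filtering, per-protein
    subsampling, reverse-mutation augmentation and homology-aware
    train/test separation; five embedding-combination regression heads
    over a pluggable protein language-model backbone with a deterministic
    mock for CPU-only testing; per-example Adam training with a linear
    warmup/decay schedule; five-model ensembling; symmetric
    (direct/reverse) evaluation with Pearson r, RMSE and MAE; and
    structure-derived test-set stratification (oligomer interfaces at a
    distance cutoff, cofactor contacts, burial and secondary structure
    from DSSP output).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
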