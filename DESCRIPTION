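Package: synkin
Title: Automated Classification of T Lymphocyte Motility Behaviors from
    Cell Tracks
Version: 0.1.0
Authors@R:
    person("synkin", "developers", email = "synkin@example.org",
           role = c("aut", "cre"))
Description: Tools to classify the motility behaviors of T lymphocytes
    interacting with target cells from time-lapse microscopy cell tracks.
    Reads per-timepoint track tables in an Imaris-export-like CSV dialect,
    computes a 90-feature sliding-window representation of each
    (cell, timepoint) sample, selects features with a minimum redundancy
    maximum relevance (mRMR) procedure whose feature count is chosen by
    grouped cross-validation, and trains a balanced random forest for
    binary (synapse versus kinapse) or three-class (poking, scanning,
    dancing) classification with experiment-level splits that prevent
    data leakage. A parametric trajectory simulator generates labeled
    fields of synthetic tracks so every pipeline stage can be exercised
    and tested without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
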