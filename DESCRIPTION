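Package: mearec
Title: Storage, Validation and Analysis of Multielectrode Array Spike
    Train Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for curating multielectrode array (MEA) recordings of
    spontaneous neural activity, such as retinal waves in developing
    retina.  Implements an HDF5 container schema for spike-sorted
    recordings (unit positions, concatenated spike trains, minimal
    metadata, cached summaries), with readers, writers and a schema
    validator; repository-level cataloguing of directories of
    recordings; pairwise correlation-index analysis as a function of
    inter-unit distance; per-train burst detection and burst-duration
    summaries; diagnostic figures (the four-panel recording overview and
    binned correlation-index family plots); and a seeded generator of
    synthetic recordings (propagating-wave and homogeneous Poisson
    activity) on standard array layouts for testing complete pipelines
    at desk scale.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    rhdf5,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
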