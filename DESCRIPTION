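Package: ravinehab
Title: Multi-Scale Habitat Modeling and Conservation Gap Analysis for
    Stream-Breeding Insects
Version: 0.1.0
Authors@R: person("FWRI", "Spatial Ecology Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to model breeding habitat for stream-breeding insects in
    dissected ravine landscapes and to quantify conservation gaps.  Derives
    multi-scale terrain, hydrology, soil and land-cover covariates from
    gridded inputs (slope, topographic position, geomorphon landforms, D8
    flow accumulation, Strahler-ordered headwater flowlines), cleans and
    spatially thins occurrence records to one presence per stream reach,
    fits an L1-regularized presence-background maximum-entropy model with
    bias-matched background sampling, evaluates it with AUC/TSS/SEDI and
    permutation importance, refines the continuous prediction into breeding
    plus terrestrial habitat, and reports protected-area coverage and
    projected-urbanization threat.  A synthetic-landscape generator with a
    known suitability truth makes the full pipeline testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
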