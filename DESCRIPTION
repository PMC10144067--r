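Package: fieldlisa
Title: Spatial Dependence Assessment of Breeding Fields from UAV Height Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess spatial dependence in plant-breeding field
    trials from UAV-style elevation rasters. Computes canopy height models
    (DSM minus DTM), extracts per-plant heights by buffer maxima, runs
    local Moran's I (LISA) with distance-band spatial weights and
    conditional-permutation pseudo p-values, delineates low/high crop
    growth cluster regions and A/B/C management zones, and compares
    replicate plots of each germplasm with rank-based tests
    (Kruskal-Wallis, Dunn's post hoc with Benjamini-Hochberg correction,
    Wilcoxon rank-sum). Includes a seeded synthetic breeding-field
    generator (layout, sloped terrain, germplasm-specific growth with an
    elevation-linked suppression, rendered DSM/DTM rasters) so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
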