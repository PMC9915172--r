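Package: exposurekit
Title: Individual-Level Environmental Exposure Indicators from Street Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes address-level environmental exposure indicators across
    eleven urban domains (air quality, road traffic, greenness, greenspace,
    public transport, food environments, land-use intensity, walkability,
    street centrality, built form and indoor dwelling qualities). Builds a
    segment-dissected pedestrian street-network model with metric and angular
    (space-syntax) shortest paths, catchments and urban blocks; supports
    exponential distance-decay accessibility measures, zonal raster statistics
    (NDVI, pollutant surfaces), Spacematrix density indices, fuzzy address
    matching to property reference numbers, and a seeded synthetic-city
    generator so the full pipeline is testable without licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
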