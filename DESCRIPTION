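Package: natscales
Title: Natural Scales of Human Movement from Geotagged Event Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the small number of natural geographic scales hidden in
    geotagged human-mobility data. Builds a weighted user co-occurrence network
    over locations, restricts it to increasing percentiles of the edge distance
    distribution, partitions every percentile graph by repeated modularity
    maximisation, smooths partitions on a Voronoi tessellation, measures
    partition similarity across the scale spectrum with a Rand index, and
    detects the phase transitions (breakpoints) that delimit natural scales.
    Exports single- and multi-scale geographic boundaries as GeoJSON and ships
    a synthetic mobility generator with planted scale regimes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
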