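Package: wheatscape
Title: Phenology-Based Winter Wheat Mapping and Climate-Driver Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping winter wheat from seasonal leaf-area-index
    (LAI) raster time series and for analysing the climate drivers of its
    planting area and yield. Implements per-pixel phenological
    classification (inflection-point and LAI-maximum threshold rules over
    three climatic periods of the growing season), multi-year planting
    frequency and frequency-change maps, relative-error accuracy
    assessment against yearbook areas, growing-season aggregation of daily
    station meteorology (accumulated temperature, precipitation, sunshine
    hours over the day-273 to day-145 window), the Mann-Kendall trend test
    with sequential UF/UB abrupt-change (mutation) detection,
    Hodrick-Prescott decomposition of annual series into trend and
    climatic components, and Pearson correlation tables with significance
    stars and driver ranking. A synthetic-data module generates LAI cubes,
    daily meteorology and area/yield series with known ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
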