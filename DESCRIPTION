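Package: microgeostat
Title: Geostatistical Analysis of Soil Microbial Communities Along Transects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landscape-scale geostatistics for soil prokaryotic communities:
    alpha-diversity and richness estimation from OTU tables with rarefaction,
    empirical semivariograms and variogram model fitting, ordinary kriging over
    a rasterized polygon with leave-one-out cross-validation, nugget/sill
    spatial-dependence classification, Mantel autocorrelograms, taxa-environment
    Spearman correlation tables, collinearity screening, and BIOENV exhaustive
    environmental-subset selection. Includes a synthetic-data generator that
    emulates a short saline lake-bed transect (spatially autocorrelated soil
    properties, compositional texture, covariate-driven taxon abundances with
    variable sequencing depth) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    ape,
    vegan,
    biomformat,
    withr,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
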