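Package: oasisdyn
Title: Oasis Change Dynamics, Constraint Frequency and Grey Incidence
    Attribution in Arid Basins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multi-decadal oasis change in arid inland
    river basins from co-registered grids: per-period areas and change maps,
    stable (intersection) and maximum (union) oasis extents, zonal area
    statistics, a distribution-frequency constraint model with Gaussian
    curve fits against terrain, hydrologic and thermal covariates, an
    accessibility water depth (AWD) grid built from gauged runoff and
    precipitation, and grey relational (grey incidence) attribution of
    oasis-area change to socio-economic and hydrologic drivers. Includes a
    seeded synthetic-basin generator with known ground truth and a staged
    file-based pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
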