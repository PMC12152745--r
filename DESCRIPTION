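Package: aeromig
Title: Radar Aeroecology of Nocturnal Bird Migration in the Tropics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for weather-surveillance-radar vertical profile
    time series of nocturnal bird migration. Partitions biological radar echoes
    into bird and insect components from reflectivity-weighted velocities and
    interpolated pressure-level winds, computes flow assistance along the
    seasonally preferred migratory direction, integrates profiles into
    vertically integrated density and migration traffic rate, and quantifies
    the steadiness versus episodicity of seasonal migration with nightly
    coefficients of variation, bootstrap confidence intervals, percent-of-nights
    and core-season passage statistics. Includes pairing of radar nights with
    nocturnal flight-call recording logs and a synthetic-data generator with a
    known ground truth (seasonal passage curve, nocturnal low-level jet,
    bird/insect velocity mixture, height-dependent call detectability) so every
    pipeline stage is verifiable without a multi-year radar archive.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
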