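Package: borealbedo
Title: Forest Composition Change and Albedo Radiative Forcing in Boreal Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping sub-pixel deciduous fraction and
    tree canopy cover from seasonal multispectral composites, modelling
    seasonal surface albedo from forest composition, converting
    epoch-to-epoch albedo change into shortwave radiative forcing with
    radiative kernels, and summarising change by fire-age chronosequence
    and region. Includes a seeded synthetic-landscape generator that
    emulates post-fire succession, mixed deciduous/evergreen reflectance
    with seasonal phenology contrast, inventory plot tables, coarse albedo
    with validity masks, and negative-valued albedo kernels, so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
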