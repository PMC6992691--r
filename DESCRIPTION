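Package: lcscreen
Title: Rapid Screening and Documentation of Least Concern Plant Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens plant species for likely Least Concern Red List status
    from georeferenced occurrence records. Resolves binomials against a
    pluggable name backbone, restricts occurrences to the native range defined
    by WGSRPD Level-3 botanical regions, computes range statistics (extent of
    occurrence as a minimum convex polygon, area of occupancy on an occupancy
    grid, record count, region count), classifies species against adjustable
    Least Concern thresholds, exports IUCN SIS Connect-compliant CSV bundles,
    and calibrates thresholds with confusion-matrix sensitivity sweeps. All
    remote services (occurrence and checklist providers) are injected
    interfaces with bundled offline fixture backends, and a synthetic fixture
    generator produces clustered occurrence clouds, toy region grids and
    validation tables for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    tibble,
    withr,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
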