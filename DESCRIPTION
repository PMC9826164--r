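Package: forestaudit
Title: Remote-Sensing Additionality Audits for Improved Forest Management Carbon Offsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to audit the additionality of improved forest management
    (IFM) carbon-offset projects from annual gridded carbon and harvest data.
    Builds spatial control groups (surrounding buffers, regional pools, and
    Mahalanobis covariate-matched pixel sets), compares carbon accumulation,
    harvest rates and species composition between project lands and controls
    before and after project initiation (trend, Chow structural-break and
    paired t statistics), and models offset crediting (initial versus
    incremental credits and break-even time). Includes a synthetic-landscape
    generator with known ground truth so the full audit is testable without
    external data, and lightweight readers and writers for ASCII-grid raster
    stacks, GeoJSON polygons and CSV project documents.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
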