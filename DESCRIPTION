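Package: namtier
Title: Tiered Hazard and Exposure Safety Assessment with New Approach
    Methodologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic decision engine for tiered chemical safety
    assessment. Classifies hazard endpoints into CLP-derived potency
    categories, derives duration-specific exposure categories A-E from band
    tables, limit doses and the substance-specific threshold of
    toxicological concern (TTC), derives DNELs from points of departure
    (in vivo or IVIVE-converted in vitro), combines hazard and exposure
    categories in a red/amber/green matrix with margin-of-exposure
    resolution, and replays complete assessment trajectories from
    structured substance dossiers and exposure scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
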