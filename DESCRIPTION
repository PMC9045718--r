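Package: borealfire
Title: Boreal Wildfire CO2 Emissions Accounting and the Economics of Fire
    Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Carbon accounting for boreal North American wildfires with
    post-fire regrowth, projection of burned area to mid-century, models of
    individual fire size as a function of fire management zone, two-stage
    instrumental-variable estimation of the spending elasticity of fire
    size, and the cost per avoided metric ton of CO2. A seeded synthetic
    fire-catalog generator emulates the statistical structure of agency
    fire and expenditure records so every stage of the analysis runs and
    is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    ranger,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
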