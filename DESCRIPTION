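Package: isofcr
Title: Stable-Isotope Indicator Traits and Genomic Analysis of Feed Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing feed efficiency in group-housed fish from
    stable-isotope tracer phenotypes. Converts delta-notation isotope
    measurements to atom percent and atom percent excess, derives individual
    indicator ratio traits (IFCR/IFER) and tank-level feed conversion ratio,
    builds individual (VanRaden method 1) and tank-level genomic relationship
    matrices, estimates variance components, heritabilities and genetic
    correlations with uni- and bivariate REML, and performs tank-level
    regression model selection by leave-one-out PRESS with backward
    elimination. Includes a family-structured synthetic-data generator with
    controllable genetic architecture for validation and power studies, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
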