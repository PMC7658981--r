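Package: corediv
Title: Phenotypic Diversity, Trait Repeatability and Core Collections for
    Perennial Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives tree- and fruit-traits from raw field measurements of
    perennial germplasm collections and analyses their phenotypic diversity:
    descriptive statistics, group-effect tests with ecological-region
    contrasts, correlation structure, standardized major axis allometry with
    slope-equality and elevation-shift tests, Hopkins clustering tendency,
    PCA with hierarchical clustering on retained components and v-test
    cluster characterization, adjusted repeatability of replicate-measured
    fruit traits by REML variance components with parametric-bootstrap
    uncertainty and boundary-corrected likelihood ratio tests, and core
    collection selection by Gower-distance average entry-to-nearest-entry
    maximization with coincidence-rate, variable-rate, variance-difference
    and mean-difference quality statistics. Includes a seeded synthetic
    germplasm generator emulating the structure of a 203-accession West
    African Synsepalum dulcificum collection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    lme4,
    withr
Config/testthat/edition: 3
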