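Package: ivyaudit
Title: Taxonomic-Certainty Audit and Curation of Ivy Occurrence Databases
Version: 0.1.0
Authors@R: person("ivyaudit", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the taxonomic certainty of species occurrence
    databases, developed around the western European ivies (Hedera L.).
    Classifies identification errors against a taxon-concept rule table
    (misidentification, soft and hard taxonomic change, records never
    identified to species), builds classification matrices and per-group
    error-rate tables with two-level chi-squared goodness-of-fit tests,
    fits a binomial GLM of identification error on species and regional
    taxonomic uncertainty, and compiles mixed reviewed/online spatial
    point databases with region filtering and distance-buffer thinning.
    Includes a seeded synthetic occurrence generator with ground-truth
    error labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
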