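Package: dolsim
Title: Individual-Based Simulation of Division of Labour in Cooperative Breeders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An individual-based evolutionary model of helping, dispersal and
    task specialization in cooperatively breeding vertebrates. Groups of one
    breeder plus totipotent subordinate helpers evolve a helping effort, a
    dispersal propensity and a dominance-dependent task-choice reaction norm
    (defensive versus work tasks with different fitness costs), under
    configurable direct (group augmentation) and indirect (kin selection)
    fitness benefits. Includes a compiled production engine, a per-individual
    reference engine with an identical random-draw contract, a replicate and
    scenario-grid runner, neutral-locus relatedness estimation, and tabular
    summary output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
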