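Package: csrep
Title: Complementarity-Based Assessment of Ecological Representation in
    Protected-Area Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for species-based gap analysis of protected-area (PA)
    networks. Builds complementary sets of planning units that jointly
    represent every species (or every threatened species) at least once,
    using a staged greedy algorithm driven by a pairwise complementarity
    score on species incidence data. Scores a PA layer against a
    complementary set with an ecological representation index, identifies
    conservation-gap units and unprotected species, summarises congruence
    and PA-coverage classes, and quantifies the robustness of site
    selection to sampling error by stratified bootstrap. Includes a
    synthetic species-occurrence simulator with heavy-tailed occupancy,
    biogeographic range cohesion and zero-inflated PA coverage, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
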