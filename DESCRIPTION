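Package: phycoflux
Title: Compartmentalized Metabolic Reconstruction and Flux Balance
    Analysis for Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building, curating and simulating compartmentalized
    genome-scale metabolic models of microalgae. Provides a stoichiometric
    network data model with five compartments (cytosol, plastid,
    mitochondrion, microbody, extracellular), a curation pipeline that
    resolves duplicate compound labels, rewrites polymer pseudo-reactions,
    assigns subcellular compartments from literature and homology evidence,
    and adds membrane transporters; SBML import/export with gene-reaction
    associations stored in reaction notes; a linear-programming flux
    balance engine with substrate-minimization and product-maximization
    problems, reaction knockouts and a parsimonious secondary objective;
    producibility screening and breakpoint tracing for network gap
    analysis; trophic-condition scenarios (autotrophic, heterotrophic,
    mixotrophic) and hydrogen-production studies including cyclic
    electron flow disruption; and a generator for a curated, elementally
    balanced algal core network used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
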