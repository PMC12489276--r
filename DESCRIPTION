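Package: algaeGEM
Title: De Novo Refinement and Flux Analysis of Algal Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomated refinement of genome-scale metabolic models (GEMs) of
    green algae: consensus voting of protein subcellular-localization predictions
    onto reactions, mixed-integer compartmentalization with minimal replicated and
    transport reactions, elimination of thermodynamically infeasible cycles while
    preserving biomass production, construction of condition-specific biomass
    reactions normalized to 1 g per g dry weight, MILP gap-filling against a
    universal reaction pool, GECKO-style enzyme constraints under a total protein
    pool, and the downstream flux analyses used to screen growth-improvement
    targets (FBA, pFBA, FVA, active-reaction calling, essentiality, flux-growth
    correlation, hit-and-run flux sampling and homolog flux comparison).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    reticulate,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
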