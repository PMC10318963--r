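Package: fpchoice
Title: Facility Choice Modelling for Family Planning Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing which health facility a woman chooses for
    family planning services, and how far she is willing to travel for better
    quality. Implements the alternative-specific conditional logit utility
    model by maximum likelihood with analytic score and observed information,
    willingness-to-travel estimates (extra kilometres per unit of a quality
    indicator) with delta-method uncertainty, straight-line distance matrices
    with a pluggable external (road-network) matrix, stock-validated facility
    quality indicators, a principal-component wealth index, descriptive
    summaries, and a synthetic-study generator (clustered women, facilities,
    Gumbel-error utility-maximising choices) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
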