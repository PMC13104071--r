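Package: permacomm
Title: Community Assembly, Networks, and Stability Along Permafrost Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for depth-resolved microbial community
    profiles from permafrost cores: alpha/beta diversity and ordination,
    null-model stochasticity ratios, Sloan neutral community model fitting,
    Levins niche overlap, SparCC compositional correlation networks with
    natural-connectivity robustness curves, average-variation-degree (AVD)
    community stability, occupancy-abundance core-taxon identification,
    permafrost degradation indexing, and stratum-adjusted associations
    between community stability and organic carbon density. Includes a
    synthetic permafrost-profile generator with known assembly regime and a
    tunable stability-carbon link so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    optparse,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
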