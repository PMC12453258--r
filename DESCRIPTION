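Package: migmix
Title: Effective Migration Surfaces with Long-Range Gene-Flow Edges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint representation of spatially heterogeneous isolation by
    distance and discrete long-range gene flow. Fits an effective migration
    surface (edge weights and deme-specific variances on a triangular deme
    lattice) by penalized Wishart maximum likelihood on observed genetic
    distances, detects deme pairs that are more genetically similar than the
    surface predicts, and models each such signal as a directional long-range
    edge with a maximum-likelihood source location and source fraction.
    Includes kriging of within-deme coalescent times at unsampled demes,
    leave-one-out spatial assignment of individuals, and a stepping-stone
    coalescent simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse
Config/testthat/edition: 3
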