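Package: senemod
Title: Integrative Modelling of Gene Regulation and Senescence Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to model the onset of plant senescence from the molecular
    to the whole-plant level. Provides synthetic-data generators with known
    ground truth (negative-binomial count matrices, expression time courses
    driven by a known regulatory network, and plant image series with a
    programmed green-to-yellow trajectory); colour-based image phenotyping
    (palette quantization, colour-frequency matrices, senescence
    trajectories); negative-binomial differential expression with
    Benjamini-Hochberg correction and candidate selection; robust sparse
    k-means clustering with observation trimming; gene regulatory network
    reconstruction by the time-lagged ordered lasso with lag-monotone
    coefficient constraints; a discrete-time gene-network simulator with
    Michaelis-Menten promoter elements and knockouts; discrimination of
    candidate network topologies by optimised Pearson-based fitness; and an
    L-system plant whose segment colours express a simulated chlorophyll
    signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
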