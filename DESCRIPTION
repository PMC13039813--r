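Package: dropletActin
Title: Agent-Based Simulation of Actin Networks in Deformable Protein Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates semiflexible, growing actin filaments confined inside a
    liquid protein droplet modelled as a dynamically deformable ellipsoid with
    surface tension and a conserved volume. Crosslinker agents (stable
    tetramers or dynamically multimerizing monomers) bind and unbind actin
    with force-sensitive (Bell's law) kinetics, and filament plus ends cap and
    uncap stochastically. Includes shape descriptors based on the gyration
    tensor (spans, alignment angle), actin-covered surface fraction on a
    deformed icosphere, filament length distributions, power-law fitting of
    deformation datasets, PCA/varimax plus K-means morphology classification
    with silhouette model selection, an equipartition mode model for the
    scaling of bundle thickness with droplet radius, and deterministic
    synthetic-data generators for testing every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    cluster,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
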