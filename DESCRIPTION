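Package: corneaMADM
Title: Quantification of MADM-Labeled Corneal Endothelial Mosaics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image quantification for mosaic analysis with double markers
    (MADM) in corneal endothelial monolayers. Provides a generative simulator
    of MADM-labeled monolayers (blue-noise cell packing, G2-X/G2-Z/G0-G1
    recombination events, genotype-specific clonal expansion and dispersal,
    fluorescence rendering), junction-image cell segmentation by convolution
    filtering and Dirichlet tessellation with morphometric readouts (area,
    circularity, neighbor counts, regional densities), red/green/yellow
    labeled-cell detection in two-channel panoramas, twin-spot discovery,
    deterministic density-based (DBSCAN-style) cluster-dispersion analysis,
    and green/red-ratio reporting across corneas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    deldir,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
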