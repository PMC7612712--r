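Package: compext
Title: Compaction-Extension Morphometrics and Cell-Track Statistics for
    the Zebrafish Presomitic Mesoderm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how the zebrafish presomitic mesoderm (PSM)
    elongates by compaction-extension rather than posterior growth.
    Implements contour-stack volumetry, stage-trendline fitting with AIC
    model selection, cumulative paraxial reconstruction, photolabel
    deformation and cell-volume comparisons; 3D nuclear spot detection
    (Laplacian-of-Gaussian) and autoregressive-motion track linking with
    gap closing; moving-reference-frame normalisation of tracks into
    anatomical AP/DV/ML coordinates; and tissue-fluidity statistics
    (k-nearest-neighbour exchange counts, neighbour-pair angle-change
    analysis with Kolmogorov-Smirnov comparison, and dorsoventral /
    mediolateral convergence regressions).  A synthetic-embryo simulator
    generates compacting half-PSM tissues, ground-truth cell tracks,
    photolabels and rendered nuclei images so that every analysis stage is
    verifiable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
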