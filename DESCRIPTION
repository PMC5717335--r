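Package: kinetoquant
Title: Quantitative Kinetochore Immunofluorescence and Label-Free
    Interactome Analysis
Version: 0.1.0
Authors@R:
    person("Kinetoquant", "Developers", email = "maintainer@kinetoquant.org",
           role = c("aut", "cre"))
Description: A pipeline for volumetric quantification of kinetochore protein
    levels from multi-channel immunofluorescence z-stacks: Otsu-based 3D
    segmentation of centromere (ACA) staining, outer-kinetochore mask
    expansion, annulus-based local background subtraction, background-
    corrected integrated intensities, per-cell summaries and the
    normality-routed two-group and Kruskal-Wallis/Dunn group statistics used
    in fixed-cell siRNA depletion experiments. A companion module performs
    label-free quantitative affinity-purification analysis (per-protein log2
    fold changes, Student's t-tests and volcano classification) on
    protein-group intensity tables. A synthetic-data generator renders
    ground-truthed 3D stacks (Gaussian point-spread spots, Poisson and read
    noise) and LFQ tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
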