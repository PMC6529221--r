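Package: lhscreen
Title: Anatomical Overlap and Optogenetic Behaviour Analysis for Lateral Horn Neuron Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the quantitative analysis used in neurogenetic screens of
    the Drosophila lateral horn. Builds binary 3D masks from registered neuron
    image stacks (overlay, contrast enhancement, Gaussian blur, Otsu
    auto-threshold), scores bidirectional voxel overlap between masks as a
    proxy for potential connectivity, clusters overlap matrices, classifies
    significant interactions, and builds modality-averaged input maps. Computes
    behavioural readouts from tracked trajectories (four-quadrant optogenetic
    preference index, locomotion deltas, Flybowl locomotion) and tethered-flight
    wingbeat traces (yaw, thrust, baseline-subtracted response traces,
    per-timepoint rank-sum tests), together with the nonparametric screening
    chain (Levene, Kruskal-Wallis with Dunn post-hoc versus control, false
    discovery rate and Bonferroni adjustment). A synthetic-data module generates
    registered volumes, arena trajectories, and wingbeat traces with known
    ground truth so every stage is verifiable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
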