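Package: tempnet
Title: Dynamic Dose-over-Time Perturbation Analysis on Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for analysing and visualizing dynamic
    (dose-over-time) perturbations on biological networks. Reads edge lists,
    0/1 adjacency matrices, Cytoscape SIF files and long-format dynamic edge
    tables with automatic format detection; models a network as an ordered
    series of frames (time points, doses, or dose-over-time combinations);
    computes directed degree centrality (inner, outer, total) per frame,
    degree-threshold filtering, first-degree neighbourhoods and persistent
    edges between frames; lays networks out with a deterministic
    force-directed spring model plus a sinusoidal z-extension to 3D; maps
    node expression to symmetric diverging colour scales and degrees to node
    sizes; assembles frame-by-frame animations exported as GIF, PNG
    sequences or standalone HTML, and per-neighbourhood expression line
    graphs; ranks pathways by network gene membership from local annotation
    tables; and ships a command-line interface and a synthetic fixture
    generator for reproducible end-to-end runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    generics,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
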