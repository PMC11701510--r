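Package: tockytraj
Title: Temporal Trajectory Analysis of Fluorescent Timer Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies elapsed time since a transcriptional event in single
    cells from two-channel Fluorescent Timer (blue/red) flow cytometry,
    integrates that temporal axis with multidimensional surface-marker
    profiles through a projection-based canonical correspondence analysis,
    and extracts time-respecting developmental trajectories by
    angle-constrained shortest-path search over a cluster network. Includes
    autofluorescence-aware PCA/k-means clustering, Tocky-locus statistics
    with Mann-Whitney tests and Benjamini-Hochberg adjustment, and a
    synthetic-data subsystem (Timer maturation/decay kinetics, Gaussian
    spike-in benchmarks, two-group cohorts with planted trajectories) so the
    whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
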