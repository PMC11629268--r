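Package: gpcrtraj
Title: Trajectory Analysis of GPCR-Transducer Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for all-atom molecular dynamics
    trajectories of G protein-coupled receptor (GPCR) complexes with
    intracellular partners (G proteins, arrestins).  Provides equilibration
    diagnostics with automatic discard-window detection, the standard set of
    class-A activation-state metrics (TM3-TM6 and TM3-TM7 distances, NPxxY
    backbone RMSD, transmission-switch distances, sodium-pocket and
    hydrophobic-lock triangle areas, ion approach and hydration counts),
    residue-wise ensemble comparison via the Jensen-Shannon distance over
    backbone and side-chain torsion distributions, a buried-surface-area
    (delta-SASA) interface protocol with membership filters and presence
    tracking, and geometric contact classification with per-replica occupancy
    averaging.  Includes a deterministic synthetic-trajectory generator that
    realises prescribed distance, torsion, burial and contact schedules with
    recorded ground truth, so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
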