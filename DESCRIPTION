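Package: qmrestraints
Title: In Situ Ligand Restraint Generation and Geometry Deviation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating ligand restraint dictionaries from the
    geometry of a ligand optimized in situ, inside its crystallographic
    binding pocket. Extracts a ligand cluster from a macromolecular model
    (whole residues and waters within a cutoff radius, including
    crystallographic symmetry images), terminates dangling bonds with
    hydrogen link atoms or zwitterionic termini, protonates waters, relaxes
    the geometry with a built-in deterministic restrained minimizer or an
    external semi-empirical engine via a file-level adapter, and rewrites
    the restraint targets of a monomer-library dictionary from the relaxed
    coordinates. Also provides periodicity-aware torsion deviation
    arithmetic, per-category r.m.s.d. geometry reports with outlier tables,
    resolution-binned summaries, and the screening rules used to select
    suitable ligand instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
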