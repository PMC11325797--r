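Package: gaswitch
Title: Interaction Networks and Stability of G-Protein Alpha-Subunit Switch Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrative biophysical analysis toolkit for disease-associated
    G-protein alpha-subunit (Galpha-S) variants. Computes hydrogen-bond
    occupancy networks between switch regions, per-residue backbone RMSF and
    inter-region nonbonded interaction energies from molecular-dynamics
    trajectories, nucleotide-proton contact occupancy profiles of the
    nucleotide-binding pocket, saturation-transfer-difference (STD) NMR
    amplification factors with error propagation and interaction binning, and
    thermal-unfolding (Boltzmann sigmoidal) and nucleotide-exchange
    (one-phase association) curve fits. Includes seeded synthetic-data
    generators with planted ground truth for every input class, and a
    pipeline that assembles per-variant reports and cross-system comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    pracma,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
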