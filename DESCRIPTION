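Package: anophore
Title: Membrane Trajectory Geometry and Transport Kinetics for Synthetic Anion Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for small-molecule anionophores studied by
    membrane molecular-dynamics trajectories and vesicle transport assays.
    Reads multi-frame coordinate trajectories (GRO, PDB, XYZ) with a JSON
    topology sidecar, computes interface-relative positions and orientations
    of transporter reference points, detects chloride-release and 180-degree
    flip events, and evaluates bilayer structural health (area per lipid,
    thickness, electron-density profiles, acyl-chain order parameters).
    Fits lucigenin chloride-influx fluorescence time courses to a
    double-exponential model yielding initial and specific initial rates,
    and fits 1:1 host-guest chloride binding isotherms from NMR titrations.
    Includes seeded synthetic-data generators with machine-readable ground
    truth for validating every detector and fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
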