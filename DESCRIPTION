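Package: eprdock
Title: Membrane Docking Geometry of Peripheral Proteins from EPR Depth
    Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers the bilayer docking geometry of a peripheral membrane
    protein from site-directed spin-labeling EPR power-saturation data.
    Converts accessibility parameters for O2 and NiEDDA into membrane depth
    parameters, models MTSSL (R1) spin-label side chains and their rotamers
    on a protein structure, and jointly fits a hyperbolic depth calibration
    together with a rigid-body transform (two rotations and a translation
    normal to the membrane) by nonlinear least squares, with outlier-driven
    rotamer refinement. Reports signed residue depths relative to the lipid
    phosphate plane, the tilt of a structural axis, bilayer-contacting
    residues by chemical class, and ligand headgroup displacement. Includes
    a synthetic-data generator emulating the 18-protein-site plus
    4-calibration-lipid study design for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
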