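# eprdock

Membrane docking geometry of peripheral proteins from EPR power-saturation
depth parameters.

## The problem

Site-directed spin labeling EPR can locate a peripheral membrane protein on
a lipid bilayer. A nitroxide spin label (MTSSL, the "R1" side chain) is
attached one site at a time across the protein surface; power-saturation
measurements give each label's collision accessibility to O₂ (which
partitions into the membrane interior) and to NiEDDA (which stays aqueous).
Their ratio defines the membrane depth parameter

    Φ = ln[ Π(O₂) / Π(NiEDDA) ]

which increases toward the membrane interior. Spin-labeled lipids (doxyl-PC
species) whose label depths are known provide the depth calibration. Given
the protein's crystal structure with modeled R1 side chains, the full set of
protein and lipid Φ values constrains a rigid-body docking pose: how deep
the protein sits and at what angle it tilts relative to the plane of lipid
phosphates.

`eprdock` implements that pipeline for desk-scale analysis and validation:

- **accessibility**: saturation-curve fitting (P½), collision parameters Π,
  depth parameters Φ with first-order error propagation;
- **spinlabel**: R1 side-chain construction on a PDB structure at any
  (χ1, χ2) rotamer (convention g⁺ = +300°, t = 180°, g⁻ = +60°), canonical
  rotamer enumeration, van-der-Waals clash detection;
- **depth_model**: the hyperbolic depth calibration
  Φ(r) = (L+B)/2 + √(((L−B)/2)² + C), L = m·r + I, composed with the
  rigid-body transform p′ = R_z(θ_z) R_x(θ_x) p + (0, Y_trans, 0);
- **docking_fit**: simultaneous nonlinear least squares for the seven
  unknowns (θ_x, θ_z, Y_trans, m, I, B, C) over one dependent variable (Φ)
  and five independent ones (x, y, z, P, D), with grid multistart,
  jackknife-based rotamer refinement and covariance/Monte-Carlo
  uncertainties;
- **geometry_report**: signed residue depths relative to the phosphate
  plane (y = 0), axis-to-plane angles, bilayer-contact residues by chemical
  class, ligand headgroup displacement;
- **synthetic_data**: a generator reproducing the study design (18 protein
  sites + 4 calibration lipids, Φ noise at measured-SEM scale) so every
  stage is testable without downloads.

The sign convention throughout: the mean phosphate plane is y = 0, positive
y is the aqueous side, membrane interior is negative.

## Worked example

```r
library(eprdock)

# depth parameters from the packaged accessibility table
tab <- read_accessibility_table(system.file(
  "extdata", "grp1_table1_synthetic_calibration.csv", package = "eprdock"))
phi <- depth_parameter_table(tab$protein)
head(phi[order(-phi$phi), ], 3)
#>    site        phi   phi_sem
#>  V278R1 0.38566248 0.1242611
#>  K282R1 0.31365756 0.1268215
#>  R322R1 0.06669137 0.1684940

# synthetic study design: simulate, fit, report
truth <- default_truth(1)
sim <- simulate_dataset(make_structure(18, seed = 1), truth,
                        sigma_phi = 0.02, seed = 1)
model <- multistart_fit(sim$dataset)
model
#> docking_model: theta_x = -12.375 deg, theta_z = -59.618 deg, y_trans = 20.280 A
#>   hyperbola m = -0.1457, i = -0.9758, b = -1.7893, c = 0.02276
#>   R = 0.9999, cost = 0.003168 (n = 22)
```

The fitted pose recovers the generating truth (−11.6°, −59.8°, +20 Å) to a
fraction of a degree/Angstrom at the measured table's noise scale, with the
correlation between measured and fitted Φ above 0.999. Applying the model
with `geometry_report()` yields per-residue signed depths, the docked-pose
PDB and contact classifications.

The numbered scripts under `analysis/` run the same workflow as a narrative
(`01_simulate.R` → `04_geometry_report.R`), writing tables under `results/`.
`run_pipeline()` drives the whole chain from one YAML/list config (see
`inst/extdata/pipeline_synthetic.yaml`).

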