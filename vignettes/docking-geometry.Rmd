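---
title: "Inferring membrane docking geometry from spin-label depth parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring membrane docking geometry from spin-label depth parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eprdock)
```

## The measurement and the model

A peripheral membrane protein bound to its target lipid sits at some depth
and tilt relative to the bilayer surface. Site-directed spin labeling EPR
constrains that pose through collision accessibilities: a nitroxide buried
in the bilayer collides often with O₂ (which concentrates in the
hydrocarbon interior) and rarely with the aqueous relaxant NiEDDA, and vice
versa for a solvent-exposed label. Power-saturation experiments quantify
each as a collision parameter Π, and the depth parameter

$$\Phi = \ln\frac{\Pi(\mathrm{O_2})}{\Pi(\mathrm{NiEDDA})}$$

rises monotonically with membrane burial. Spin-labeled lipids with labels at
known acyl-chain positions (doxyl-PC species) anchor the depth scale.

Empirically, Φ depends on the signed distance $r$ from the lipid phosphate
plane as a two-regime curve: linear deep in the membrane, constant
(plateau) in water, with a smooth elbow between. We model this as the
rectangular-hyperbola smooth maximum

$$\Phi(r) = \frac{L + B}{2} + \sqrt{\left(\frac{L - B}{2}\right)^2 + C},
\qquad L = m\,r + I,$$

which is exactly $\max(L, B)$ at $C = 0$ and rounds the elbow for $C > 0$.
$m$ (Φ-units/Å, negative: Φ rises toward the interior) and $I$ are the
slope and intercept of the linear branch, $B$ the aqueous plateau, $C \ge
0$ the curvature. Published descriptions of this calibration do not pin
down whether the curvature enters as $C$ or $C^2$ (or $4C$) under the
radical; any such re-parameterization only rescales the fitted curvature,
so the simplest form is used.

The pose enters through a rigid-body transform. With the protein centered
at the origin (unweighted mean of protein ATOM records; ligand and waters
excluded — the choice shifts only the absolute value of the translation),
the phosphate plane is the x–z plane and

$$p' = R_z(\theta_z)\,R_x(\theta_x)\,p + (0, Y_\mathrm{trans}, 0).$$

Rotations are standard right-handed matrices about +x and +z ("counter-
clockwise looking down the positive axis toward the origin"); angles are
degrees externally, radians internally. For a protein label the membrane
position is the y component of its transformed nitroxide coordinates; for a
calibration lipid it is the known depth $D$ (negative below the plane), so
one composite equation with dependent variable Φ, independent variables
(x, y, z, P, D) — P the protein/calibration indicator — and seven unknowns
$(\theta_x, \theta_z, Y_\mathrm{trans}, m, I, B, C)$ covers every row.
Because the membrane is planar, translations in x/z and rotations about y
change nothing; the identifiable angular content of $(\theta_x, \theta_z)$
is the direction of the membrane normal in the body frame.

## Fitting

`fit_docking()` minimizes the unweighted sum of squared Φ residuals with
Levenberg–Marquardt (minpack.lm). Unweighted is the default because
published per-site Φ SEMs are not reproducible from the printed Π SEMs
(one site pairs Π(Ni) = 1.18 ± 1.11 with Φ ± 0.01), so inverse-variance
weights would encode a guess; `weighted = TRUE` enables 1/σ² weights when
trustworthy SEMs exist. The curvature is kept ≥ 10⁻⁹ by a box bound —
at the $C \to 0$ degeneracy the objective loses differentiability at the
elbow. Fitted angles are wrapped to (−180°, 180°] and canonicalized to the
$\cos\theta_z \ge 0$ branch: $(\theta_x + 180°, 180° − \theta_z)$ produces
the identical physical pose, and a fixed representative makes recovery
checks well-defined.

Identifiability requires ≥ 3 protein rows with spread nitroxide positions
(to resolve the transform) *and* ≥ 2 calibration rows (the lipid anchors
pin $m$ and $I$ separately from $Y_\mathrm{trans}$; without them
$I$ and $m Y_\mathrm{trans}$ are confounded). `fit_docking()` refuses
datasets below this floor.

`multistart_fit()` guards against local minima with a 5 × 5 angle grid over
{−90°, −45°, 0°, 45°, 90°}², each point seeding a local search from both
its stated orientation and the antipodal membrane normal
$(\theta_x + 180°, -\theta_z)$ — depth data cannot steer a local optimizer
across hemispheres, so a hemisphere-blind start family is required (on the
synthetic design, noiseless truth is reached from every grid point with the
antipodal seed, from ~70% without). The remaining five parameters are
initialized from the data: $(m, I)$ by a straight line through the
calibration rows, $B$ from the most aqueous protein Φ, $C$ at its floor,
and $Y_\mathrm{trans}$ so the median protein label lands at the
linear-branch position implied by the median Φ.

### Rotamer refinement

The R1 side chain is built from internal coordinates: χ1 (N–Cα–Cβ–Sγ) and
χ2 (Cα–Cβ–Sγ–Sδ) are free in the canonical states — here g⁺ ≡ +300°,
t ≡ 180°, g⁻ ≡ +60°, with (g⁺, g⁺) the crystallographically preferred
default — and everything beyond χ2 is fixed template geometry, terminating
in the nitroxide nitrogen ~7 Å from Cα. Sterics are the only gate on
rotamer acceptability: a pair clashes when closer than the sum of
van-der-Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å) minus a 0.4 Å
tolerance, excluding pairs within 3 bonds of the attachment.

A misassigned rotamer shows up as one site disagreeing with the consensus
hyperbola. `refine_rotamers()` diagnoses this with jackknife residuals:
for each protein site the model is refitted without that site (warm start
from the current model plus a coarse 3 × 3 angle multistart) and the site's
Φ compared against that model's prediction. This matters because a
high-leverage outlier drags the 7-parameter fit enough to hide inside its
own plain residual, and inflates the plain RMS enough to hide under an
RMS-scaled threshold — hence the default threshold is
max(0.3 Φ-units, 2 × MAD of the jackknife residuals). Candidate rotamers
for a flagged site are the clash-free canonical states (falling back to
least-clashing if none), evaluated under the site's leave-one-out model;
one change is applied per round — the one that most lowers the refitted
cost — because while a bad rotamer is still in the data *every*
leave-one-out model is somewhat distorted and simultaneous multi-site
changes mis-select. Rounds are accepted only if the cost strictly
decreases, so the objective is monotone; iteration stops at quiescence or
after `max_rounds` (default 5, matching the scale on which a small subset
of sites needs adjustment). Ties in rotamer selection follow the canonical
preference g⁺ < t < g⁻ on χ1 then χ2, for determinism.

### Uncertainties

Two estimators are provided and neither is privileged:
`method = "covariance"` scales the inverse Gauss–Newton Hessian by the
residual variance; `method = "montecarlo"` refits ≥ 200 datasets resampled
with Gaussian Φ noise at per-row SEMs. On the well-conditioned synthetic
design they agree within a factor of two (tested); on 68%-interval
coverage the covariance intervals sit near nominal.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. `make_structure()` builds ~140 backbone pseudo-residues
(N, Cα, C, Cβ) on an ellipsoid with semi-axes (30, 22, 19) Å by a
deterministic golden-spiral layout. The size was chosen so that the
*surface density* of pseudo-residues matches a real globular domain: a
~140-residue β-sandwich exposes roughly half its residues on a smaller
surface, and since the pseudo-body places all residues on the surface, the
area is doubled to keep ~50 Å² per surface residue. Cβ points along the
outward normal at each site because real labeling positions are chosen
solvent-exposed; label arms therefore project into solvent, as they must
for any site a spectroscopist would label. Label sites carry nitroxide
positions 6.5–8.5 Å off the backbone.

`default_truth()` fixes the conditions: rotations (−11.6°, −59.8°) at the
published solution's scale; $Y_\mathrm{trans} = +20$ Å, which for this body
reproduces the *shallow-docking* regime the measurements show — protein Φ
spanning about −1.8 to +0.5 with the deepest labels just past the phosphate
plane (a smaller translation would sink the body tens of Å into the
bilayer, a regime in which the plateau would never be sampled and $B$
would be unidentifiable); hyperbola $(m, I, B, C) =
(−0.15, −1.05, −1.8, 0.04)$ so the plateau matches the most aqueous
measured values and the calibration depths {−8, −11, −13, −16} Å (doxyl
scale; the true depths are not published, so these are synthetic stand-ins)
sit on the linear branch; Gaussian noise on Φ of SD 0.02, the measured SEM
scale. Noise is applied to Φ, not Π, because the fit consumes Φ; Π-level
noise is exercised separately through the accessibility module's end-to-end
tests. All randomness is seeded and generators restore the caller's RNG
state.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real β-sandwich topology and side-chain packing
(clash statistics on the pseudo-body are harsher than on a real surface);
backbone flexibility; correlated or non-Gaussian Π errors; membrane
curvature, per-leaflet asymmetry or fluctuating surfaces; and any
systematic error in the published calibration depths.

## Validation summary

The test suite establishes, among other properties: exact reproduction of
closed-form oracles for every primitive (ln-ratio, hyperbola, rotations,
dihedral set-then-measure, clash rule vs. an independent all-pairs scan);
first-order Φ-SEM propagation within 5% of 10⁵-draw Monte Carlo at relative
SEMs < 0.2; exact seven-parameter recovery from noiseless synthetic data via
the default multistart (residual RMS < 10⁻⁸, R = 1); replicated noisy
recovery at σ_Φ = 0.05 with membrane-normal misorientation RMSE ≈ 1.1°,
$Y_\mathrm{trans}$ RMSE ≈ 0.36 Å and biases far below the Monte-Carlo
spread; and exact recovery of a planted non-default rotamer by the
refinement loop, with strictly decreasing cost. Recovery quality for the
two angles is reported both per coordinate and as the misorientation of
the fitted membrane normal; the latter is the physically meaningful
metric, since the $\theta_x$ coordinate carries a $1/\cos\theta_z$ metric
inflation (at $\theta_z \approx −60°$, a factor ~2), exactly as longitude
degrades near a pole.

Replicated experiments use 100 replicates of the 22-row design and the
SEM-propagation oracle uses 10⁵ draws; these sizes make the full suite and
the acceptance script each run in minutes on one CPU while leaving the
Monte-Carlo error well below the asserted margins.

## Known limitations

The recomputed Φ values agree with the published table only to within the
2-decimal rounding of the printed Π columns (max |ΔΦ| ≈ 0.076); the
published per-site Φ SEMs cannot be audited at all (see above), so the
package reports propagated SEMs and accepts user-supplied ones verbatim.
The full published pose (−11.6°, −59.8°, −50.2 Å against the crystal
structure) is not reproducible at desk scale: it depends on the original
analysis's spin-label template coordinates, its center-of-mass convention
(a −50.2 Å translation is consistent with an uncentered or differently
centered frame — for a body centered at its own mean, that translation
would bury the protein), and calibration depths that were never printed.
What is checked instead is the full *procedure* under controlled synthetic
conditions, plus the rotation-convention arithmetic that the published
transform presupposes. Headgroup twist/tilt definitions (ring normal vs.
bilayer normal; azimuth of a ring-fixed vector) are fixed and documented
here but may differ by convention from other work, so displacement angles
should be compared only within one convention.
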