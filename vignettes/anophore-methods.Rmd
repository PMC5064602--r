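---
title: "Methods: membrane geometry, transport kinetics and binding analysis for anion carriers"
author: "anophore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane geometry, transport kinetics and binding analysis for anion carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anophore)
```

# Scope and model system

`anophore` implements the analysis layer for studies of mobile-carrier
anion transport: a lipophilic receptor (here, a *trans*-decalin scaffold
bearing two aryl thiourea arms with variable *n*-alkyl substituents) binds
chloride at one water/lipid interface of a POPC bilayer, diffuses across,
and releases it at the other. Three kinds of data meet in such a study —
membrane MD trajectories, vesicle chloride-influx fluorescence traces, and
NMR binding titrations — and the package provides one tested implementation
of each analysis plus seeded generators that emulate all three inputs with
ground truth. The MD engine itself (force fields, charges, thermostats) is
out of scope: trajectories enter as coordinate files.

# Interface-relative geometry

## Reference points and sign convention

All positional analysis is relative to **P_int**, the centre of mass of one
leaflet's phosphorus atoms, taken as the water/lipid interface. Five
reference centres of mass track the transporter and its cargo: the decalin
skeleton carbons (the hydrophobic core), the four thiourea nitrogens (the
binding site), the *para*-phenylene carbons (the aromatic rim), the
terminal carbons of the alkyl tails, and the chloride.

Signed distances place the interface at 0 with **positive values toward the
bilayer core** and negative values on the water side. The underlying data
only constrain distances to an interface plotted at z = 0; whether values
are signed or folded magnitudes is not determined by them, so the signed
convention is a package decision, fixed and documented rather than
inferred.

The "closest interface" is chosen **per frame by decalin-COM proximity**,
and the chloride is referenced to the transporter's interface rather than
its own. Tying the two avoids a discontinuity at the midplane where the
chloride's own closest leaflet would switch while it is still bound.
Near the midplane the choice is genuinely ambiguous for any convention;
recovery tests against generator truth therefore score the settled part of
the path.

Leaflets are assigned once, in the first frame, by the sign of each
phosphorus z against the mean phosphorus z, and held fixed: lipid flip-flop
has a characteristic time far beyond the hundreds of nanoseconds these
trajectories span. A bilayer whose two putative leaflets are separated by
less than 6 Å is rejected as degenerate. Centre-of-mass computations unwrap
each group by the minimum-image convention about its first member
(orthorhombic boxes only), valid while a group spans less than half the
box — always true for these molecular groups.

## Orientation, release and flips

- **Orientation.** The margin m = d(decalin) − d(p-C) is positive when the
  aromatic rim sits closer to the interface than the decalin core. The
  default call threshold is 1.5 Å: |m| at or below it is "no preferential
  orientation", matching the qualitative middle class of the homologous
  series (short chains orient toward the water, long chains away, the
  middle shows no preference). The threshold is half the 3 Å margin that
  separates the clear-cut classes, and is exposed as a parameter.
- **Release.** The chloride is "released" at the first time its distance to
  the thiourea-N COM exceeds a cutoff continuously for a dwell time.
  Defaults: cutoff 6.0 Å (comfortably beyond the ~2–3.5 Å bound/solvated
  contact range), dwell 1.0 ns (long enough to ignore transient excursions,
  an order of magnitude shorter than the <15 ns release times it must
  resolve). No numeric criterion exists in the source data; both values are
  package defaults exposed as arguments.
- **Flips.** The orientation angle θ(t) is measured between the
  decalin→thiourea-N axis and the outward normal of the closest leaflet. A
  flip is a transition between *established* states — θ below 60° (binding
  site at the water) and above 120° (inverted) — where a state counts as
  established only when it persists ≥ 2 ns. The 60°/120° hysteresis band
  and the dwell both suppress double counting; any true 180° inversion
  crosses the whole band. Flip counts are non-increasing in dwell by
  construction (shorter-lived states drop out first).

# Bilayer health metrics

Four standard structural checks verify that an embedded solute leaves the
membrane unperturbed: area per lipid Lx·Ly/(N/2); P-to-P thickness (the
package's definition — a phosphate-plane separation, not a Luzzati
thickness); the electron-density profile, binned about the instantaneous
per-frame midplane so bilayer drift does not smear it, normalised to
e/Å³ (its integral times the lateral area must return the total electron
count to better than 1%, and this conservation is asserted in the tests);
and acyl-chain order parameters S_CD = ⟨(3cos²θ − 1)/2⟩ per carbon
position, averaged over hydrogens, lipids and frames, reported as −S_CD.
The limits S_CD = 1 (C–H parallel to the normal), −0.5 (in-plane) and 0
(isotropic) are exercised directly in the suite, the isotropic case against
a 10⁵-sample Monte-Carlo oracle.

# Transport kinetics

The lucigenin assay encloses a halide-sensitive dye in LUVs; chloride
influx quenches it, so y(t) = F₀/F grows from 1. The package fits

y(t) = 1 + A1·(1 − e^(−k1·t)) + A2·(1 − e^(−k2·t))

over 0–500 s. The published analysis names only "a double exponential
function" of F₀/F; this monotone-saturating form is the package's choice
because it matches the observed growth shape and has an analytic initial
slope. The **initial rate** A1·k1 + A2·k2 (s⁻¹) is insensitive to that
choice of parameterisation — any form with the same slope at t = 0 gives
the same number, which is why the specific rate is defined on the initial
slope in the first place. The **specific initial rate [I]** divides each
experiment's initial rate by its transporter/lipid mole ratio and averages
across experiments at different loadings.

Fitting is deterministic multi-start least squares: rate-constant pairs
from a 5-point log-spaced grid spanning 10⁻⁴–10⁻¹ s⁻¹ (all ordered pairs),
amplitudes solved by linear least squares at each fixed pair, and the best
start refined by Levenberg–Marquardt with tight tolerances; residual ties
break toward the smaller slow rate. Components are reported with k1 ≥ k2;
coincident rate constants are flagged as degenerate (amplitudes then act
only through their sum, leaving the initial rate well conditioned). On
noiseless synthetic traces the fit returns all four parameters to four
significant figures; at 0.5% fractional noise on F the median initial-rate
error across 50 seeds is below 1%.

When computed rates are compared against values printed at fixed precision,
`roundHalfAway()` rounds half away from zero (2.55 → 2.6), the convention
of printed chemical tables, rather than R's round-half-even.

# Binding isotherms

For H + G ⇌ HG with association constant Ka, the bound fraction follows the
exact quadratic solution

[HG] = ((H₀ + G₀ + 1/Ka) − sqrt((H₀ + G₀ + 1/Ka)² − 4·H₀·G₀)) / 2,

verified in the tests against a root-finding oracle to 10⁻¹⁰. The observed
shift is δ_free + (δ_bound − δ_free)·[HG]/H₀; fitting uses the same
grid-multi-start strategy (17 Ka candidates, 1–10⁸ M⁻¹, shifts linear at
fixed Ka) refined in log₁₀(Ka), with the standard error mapped back by the
delta method. Per-point H₀ supports host dilution during titration. A flat
isotherm raises an identifiability error instead of returning an arbitrary
Ka; fits that never pass 80% saturation are reported with a warning, since
Ka and δ_bound then trade off. The titration generator's default 12-point
schedule to 10 equivalents at 2 mM host takes Ka ≈ 7×10² M⁻¹ (the magnitude
measured for this series in wet DMSO) past 90% saturation.

# Synthetic data: what it emulates, and what it does not

The trajectory generator is a **geometric emulation, not a simulation**: no
forces, no thermostat. Its default recipe mirrors the simulated study
system — 128 POPC lipids, a 6500-molecule water slab (represented as inert
electron-density filler), 18 Na⁺/18 Cl⁻ bystander ions, phosphorus leaflets
near ±19 Å in a 62×62×70 Å box, 150 ns at 0.1 ns/frame, and a bound
chloride released within the first 15 ns. Reference-point COMs follow a
prescribed exponential approach from the bilayer core to a 6 Å equilibrium
depth (relaxation time 10 ns), with the orientation margin constant along
the path; flips are smooth logistic inversions of the axis angle; each atom
is scattered about its group's prescribed COM with 1.0 Å placement noise.
Per-leaflet static z offsets are centred so the realised phosphorus planes
average exactly ±z_P, keeping the thickness truth unbiased. Everything
prescribed is recorded in a manifest, so detectors are scored against known
truth.

What passing these tests shows is that the *analysis* is correct: distances,
averages, classifications and event detections recover what was put in, at
the stated noise. What it cannot show is anything about real lipid physics —
correlated lipid motion, undulations, chloride solvation shells, force-field
quality. Those belong to the MD engine, which this package deliberately does
not model. The fluorescence generator likewise adds Gaussian noise with sd
`noise_sd · F₀` to F (so the noise on y scales as y²·noise_sd) — real traces
carry photobleaching drifts and correlated noise it does not emulate.

Every generator takes a mandatory seed, restores the caller's RNG state,
and is bitwise reproducible.

# Problem sizes and test design

The validation suites run on deliberately small systems — typically 32
lipids, no water filler, 10–20 ns at 0.1 ns/frame, with 20–50 seeds per
sweep — chosen so the full suite completes in well under a minute while the
recovery statistics (orientation label in ≥95% of runs at margin 3 Å/noise
1 Å; release times within ±2 frames; flip counts exact; kinetic rates to
<5% median at 0.5% noise; Ka to <10% median at 0.002 ppm noise) are already
tight at those sizes. The generator defaults stay at the full study
conditions; the scaled-down recipes are explicit in each test.
`scripts/acceptance.R` re-runs the same computations end to end from a
single command-line seed and writes the headline numbers as JSON.

# Known limitations

- Orthorhombic boxes only; triclinic cells are not unwrapped.
- Leaflet assignment is frame-0-fixed; systems with real flip-flop or pore
  formation would need per-frame reassignment.
- The P-to-P thickness and the interface-at-P_int definition are
  conventions; comparing against literature values computed with other
  definitions requires care.
- The double-exponential form is one of several parameterisations with the
  same initial slope; amplitudes and rate constants individually should not
  be over-interpreted, only their slope combination.
- No AMBER binary formats (NetCDF/prmtop); trajectories must be text
  (GRO/PDB/XYZ) with the JSON sidecar.
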