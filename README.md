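# anophore

Analysis toolkit for synthetic **anionophores** — small molecules that carry
chloride across phospholipid bilayers — studied by the two complementary
routes this field relies on: atomistic membrane molecular-dynamics
trajectories, and lucigenin-based chloride-influx assays in large
unilamellar vesicles (LUVs). The package was built around a homologous
series of *n*-alkyl-substituted dithioureidodecalin carriers (labelled
7a–7f, R = H to *n*-decyl in two-carbon steps) whose transport activity
rises and falls with chain length, peaking sharply at the hexyl member.

## What it computes

**Membrane trajectory geometry.** For a bilayer + transporter + chloride
trajectory (GRO, multi-MODEL PDB, or multi-frame XYZ, with a JSON topology
sidecar naming the atom groups), the package computes the signed distance of
five reference centres of mass — decalin skeleton carbons, thiourea
nitrogens, *para*-phenylene carbons, alkyl-tail terminal carbons, and the
chloride — to the closest water/lipid interface, defined as P<sub>int</sub>,
the centre of mass of that leaflet's phosphorus atoms. The convention is
0 at the interface, positive toward the bilayer core. From these series it
derives:

- pooled replicate averages over a time window (mean ± SEM);
- an orientation class from the margin *m* = d(decalin) − d(*p*-C):
  `toward_interface` (*m* > threshold: aromatics angled at the water),
  `away_from_interface` (*m* < −threshold), or `none`;
- chloride **release events** — first time the Cl⁻–thiourea-N distance
  exceeds a cutoff (default 6 Å) for a dwell time (default 1 ns);
- **flip events** — 180° inversions of the binding-site axis relative to the
  outward membrane normal, detected with angular hysteresis
  (enter 60° / exit 120°, dwell 2 ns).

**Bilayer health checks.** Area per lipid L<sub>x</sub>L<sub>y</sub>/(N/2),
P-to-P bilayer thickness, electron-density profiles about the instantaneous
midplane, and acyl-chain deuterium order parameters
S<sub>CD</sub> = ⟨(3cos²θ − 1)/2⟩.

**Transport kinetics.** Lucigenin fluorescence decays are normalised to
y = F₀/F and fitted (0–500 s) to a double-exponential growth

    y(t) = 1 + A1·(1 − exp(−k1·t)) + A2·(1 − exp(−k2·t))

whose slope at t = 0, A1·k1 + A2·k2, is the **initial rate** (s⁻¹); dividing
by the transporter/lipid mole ratio and averaging over experiments gives the
concentration-independent **specific initial rate [I]**.

**Binding.** 1:1 host–guest chloride isotherms from ¹H NMR titrations,
using the exact quadratic solution for the bound fraction, fitted for
K<sub>a</sub>, δ_free and δ_bound.

**Synthetic data.** Seeded generators emulate every input — a two-leaflet
phosphorus distribution, prescribed transporter reference-point paths with a
chosen orientation, injected release and flip events, double-exponential
fluorescence traces, and noisy titrations — each with a machine-readable
ground-truth manifest, so every detector and fitter is validated against
known truth.

## Worked example

```r
library(anophore)

# synthetic membrane trajectory: aromatics-toward transporter, Cl- released at 8 ns
rc  <- trajectoryRecipe(n_lipids = 32, n_waters = 0, n_ion_pairs = 0,
                        duration = 20, orientation = "toward", margin = 3,
                        release_time = 8, n_chain_carbons = 2, seed = 42)
g   <- genBilayerTrajectory(rc)
ser <- referenceDistanceSeries(g$traj, g$topo)
avg <- averageReferencePositions(ser, c(15, 20))
avg
#> Average reference positions over [15,20] ns (51 frames pooled)
#>   d_decalin     8.36 +/- 0.068 Angstrom
#>   d_NH          6.58 +/- 0.084 Angstrom
#>   d_pC          5.15 +/- 0.086 Angstrom
#>   d_tail       10.06 +/- 0.066 Angstrom
classifyOrientation(avg)
#> Orientation: toward_interface (margin 3.21 Angstrom, threshold 1.50)
detectRelease(g$traj, g$topo)
#> Chloride release at 8.10 ns (cutoff 6.0 Angstrom, dwell 1.0 ns)
```

The average block reads: over the final 5 ns, the *para*-carbons sit 5.2 Å
below the phosphate plane, the decalin 8.4 Å — the binding site is angled
toward the water (margin 3.2 Å > 1.5 Å threshold), the orientation the
unsubstituted carrier adopts. The injected 8 ns release is recovered one
frame late.

```r
# kinetics: noiseless double-exponential trace, parameters recovered exactly
k <- genFluorescenceTrace(0.6, 0.02, 0.9, 0.002, noise_sd = 0, seed = 1)
fitDoubleExponential(normalizeTrace(k$trace), c(0, 500))
#> Double-exponential fit of F0/F over [0,500] s
#>   A1 = 0.6  k1 = 0.02 1/s
#>   A2 = 0.9  k2 = 0.002 1/s
#>   initial rate = 0.0138 1/s (se 2.2e-18), residual rms 2.15e-16

# specific initial rate of the hexyl carrier from its two measured loadings
specificInitialRate(data.frame(ratio = c(1/2500, 1/1000),
                               initial_rate = c(0.0031, 0.0068)))
#> Specific initial rate I = 7.27 1/s (sem 0.47, n = 2)
```

The bundled measured table (`decalinTransportData()`) carries the published
per-loading initial rates for all six carriers; `buildSummaryTable()`
assembles them into the activity summary, whose maximum falls at the hexyl
member (chain length 6).

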