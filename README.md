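# bilayr

Structural and dynamical analysis of lipid bilayer molecular-dynamics
trajectories, in R.

`bilayr` is aimed at membrane simulators who want the standard battery of
bilayer observables — and a way to *prove* those observables are computed
correctly. It covers the quantity set used to characterise a
phosphatidylcholine-type bilayer (e.g. POPC) against a chemically modified
analogue such as an arsenocholine lipid (POAC):

* **Area per lipid** ⟨A⟩ = Lx·Ly / n<sub>leaflet</sub>, per frame, with
  windowed averaging of the trace.
* **Membrane thickness** ⟨T⟩: for every lipid, the shortest 3-D distance
  from its headgroup phosphorus/arsenic to the headgroup atoms of the
  opposite leaflet (minimum-imaged laterally), averaged over lipids and
  frames.
* **z-density profiles** of named atom groups about the bilayer center.
* **Radial distribution functions** g(r) = N(r) / (4πr²ρδr) under the 3-D
  minimum-image convention, with per-frame density normalization for
  constant-pressure boxes.
* **Coordination counts**: the hydration number ⟨H⟩ (water oxygens within
  4.85 Å of each headgroup center) and the inter-lipid salt-bridge count
  (choline nitrogens within 6.75 Å of an As/P of a *different* lipid) —
  both cutoffs chosen to enclose the first g(r) peak.
* **Deuterium order parameters** S<sub>CD</sub> = ½⟨3cos²θ − 1⟩ per acyl
  carbon, for the sn-1 and sn-2 chains, in the C–H bond or C-neighbor
  segmental-vector convention.
* **Headgroup rotational autocorrelation** RAF(t) = ⟨v̂<sub>P→N</sub>(t₀) ·
  v̂<sub>P→N</sub>(t₀+t)⟩ over all lipids and time origins, fitted to the
  Kohlrausch–Williams–Watts stretched exponential exp(−(t/τ)^β) via the
  linearized ln(−ln RAF) vs ln t least-squares fit.
* **Headgroup tilt** statistics against the outward leaflet normal.
* **Lateral diffusion** D<sub>xy</sub> = slope/4 of the multi-origin,
  COM-unwrapped lateral mean-square displacement (reported in Å²/ns and
  cm²/s).

Because published bilayer trajectories are rarely deposited, the package
ships a **synthetic bilayer generator** (`generate_bilayer()`) whose every
statistical property is planted: Brownian lateral motion with known
D<sub>xy</sub>, rotational diffusion of the P→N vector with a target tilt
distribution, chain C–H vectors drawn at the inverse-P2 angle
θ\* = acos(√((2S\*+1)/3)) so each carbon's S<sub>CD</sub> is exact, a
planted hydration shell and (optionally) planted inter-lipid salt bridges.
Every analysis function is validated by parameter recovery against this
ground truth plus brute-force oracles — no MD engine required.

Trajectory I/O: multi-model PDB (with `CRYST1`, per-frame boxes supported)
and CHARMM/NAMD-dialect DCD, read and write; atom roles are assigned by a
rule file so POPC, POAC and arbitrary lipid chemistries share one code
path. All results are tibbles with `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(bilayr)

spec <- synthetic_bilayer_spec(n_frames = 300, n_waters = 2000, seed = 42)
traj <- generate_bilayer(spec)
traj
#> <bilayer trajectory> 12010 atoms x 300 frames, t = [0, 1.495] ns, box[1] = (50.01, 50.01, 90.00) A

res <- run_full_analysis(traj)
res
#> <bilayer analysis summary>
#>   area per lipid     : 52.72 +/- 0.30 A^2
#>   membrane thickness : 44.80 +/- 0.00 A
#>   hydration number   : 16.86 waters/lipid (cutoff 4.85 A)
#>   salt bridges       : 1.68 per lipid (cutoff 6.75 A)
#>   mean S_CD          : sn-1 0.174, sn-2 0.124
#>   headgroup tilt     : 72.1 +/- 26.1 deg
#>   KWW relaxation     : tau = 0.6559 ns, beta = 0.911
#>   lateral diffusion  : 0.7022 A^2/ns = 7.022e-08 cm^2/s
```

Reading the numbers: the box was sized for ~53 Å² per lipid and the
leaflets planted 44.8 Å apart, and both come back exactly. The hydration
number is the 11 planted shell waters per lipid plus waters of neighbouring
lipids that fall inside the 4.85 Å cutoff. The generator's rotational
diffusion (D\_r = 1 ns⁻¹) relaxes the headgroup on the sub-ns scale, so the
fitted KWW τ ≈ 0.66 ns with β ≈ 0.9 (β < 1 reflects the tilt-restoring
term); the planted lateral diffusion coefficient 0.675 Å²/ns is recovered
within the per-run sampling scatter. Individual stages (`area_per_lipid()`,
`membrane_thickness()`, `scd_profile()`, `head_vector_raf()` + `kww_fit()`,
`msd_lateral()` + `diffusion_fit()`, `radial_distribution()`,
`coordination_number()`, ...) return the same numbers as the driver, as
tibbles ready for dplyr/ggplot2 (`autoplot(res$area)` etc.).

A command-line front end wrapping the same functions lives at
`inst/cli/bilayer.R`:

```sh
Rscript inst/cli/bilayer.R simulate --spec spec.cfg --seed 1 --out-pdb topo.pdb --out-dcd traj.dcd
Rscript inst/cli/bilayer.R run --topology topo.pdb --traj traj.dcd --out-dir results/
```

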