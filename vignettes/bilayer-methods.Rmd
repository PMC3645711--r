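---
title: "Bilayer trajectory analysis: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilayer trajectory analysis: models, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayr)
```

`bilayr` computes the standard structural and dynamical observables of a
lipid bilayer from an all-atom trajectory, and validates every one of them
by parameter recovery on synthetic trajectories with planted ground truth.
This vignette is the package's account of the underlying models, the
estimator choices, the synthetic-data model and its limits, and the design
decisions taken where conventions genuinely diverge.

## Coordinate conventions

Coordinates are in ångström, times in nanoseconds. The bilayer normal is
fixed to the **z axis**; no director fitting is attempted, matching the
usual setup where the membrane is assembled in the xy plane and held there
by the barostat. Boxes are orthorhombic `(Lx, Ly, Lz)`, per frame; triclinic
cells are rejected outright rather than silently mishandled.

One consequence that is easy to get wrong: trajectories are usually stored
with coordinates *wrapped* into the box. Any intramolecular vector
(headgroup P→N, chain C–H) computed naively from wrapped coordinates is
corrupted whenever a molecule straddles a boundary, which quietly distorts
rotational correlation functions and order parameters. All bonded vectors
in `bilayr` are therefore minimum-imaged per frame.

## Structural observables

**Leaflet assignment** (`assign_leaflets()`): a lipid is "upper" iff the z
of its headgroup center is at or above the z centroid of all headgroup
centers in a reference frame; the assignment is then frozen. Lipid
flip-flop occurs on timescales far beyond the hundreds of nanoseconds
analysed here, so tracking it would only add noise.

**Area per lipid** (`area_per_lipid()`): `Lx·Ly / n_leaflet` per frame.
When the two leaflets hold different numbers of lipids the two per-leaflet
values are averaged.

**Membrane thickness** (`membrane_thickness()`): for each lipid, the
shortest full 3-D Euclidean distance between its headgroup center atom and
all headgroup center atoms of the opposite leaflet, minimum-imaged in x and
y only — imaging in z would wrap a distance across the water slab and
corrupt the minimum. The per-frame value averages these shortest distances
over the lipids of *both* leaflets by default; whether the original
convention averaged one leaflet or both is ambiguous, so the symmetric
choice is the default and `leaflet = "upper"/"lower"` exposes the
single-leaflet variant.

**Density profiles** (`density_profile()`): histograms of `z − z_center`
(signed, default) or `|z − z_center|`, where the bilayer center is the
per-frame z centroid of all headgroup centers; normalized to atoms per
frame per ångström, so the profile integrates back to the selection size.
Default bin width 0.5 Å — fine enough to resolve headgroup/carbonyl/water
structure, coarse enough not to be sampling-noise-limited on 10²-frame
windows.

**Analysis window**: every function takes `window = c(start, end)` in ns and
defaults to the latter half of the trajectory, the usual production-window
convention for bilayer runs that equilibrate their area during the first
half. `window_average()` provides the conventional centered moving-average
smoothing (default 5 ns) for presentation of ⟨A⟩ and ⟨T⟩ traces; windows
are truncated (not padded) at the series edges.

## Pair statistics under periodic boundaries

`radial_distribution()` implements `g(r) = N(r) / (4π r² ρ δr)` with 3-D
minimum-image distances. Two details:

* ρ is the *instantaneous* per-frame number density of the second
  selection. Constant-pressure boxes breathe, so each frame's shell counts
  are normalized by that frame's density before averaging (a per-frame
  `N(r)/ρ` accumulation); with a constant box this reduces exactly to the
  textbook formula.
* `r_max` may not exceed half the smallest box edge over the window, where
  the minimum-image metric stops being a metric. Default shell thickness
  δr = 0.1 Å.

`coordination_number()` counts, per reference atom, the second-selection
atoms within a cutoff. With `exclusion = "same_residue"` intra-lipid pairs
are discarded; that turns the As/P-to-choline-N count into the
**inter-lipid salt-bridge count**. The salt bridge is operationalized
purely as this cutoff count (6.75 Å, enclosing the first g(r) peak) — no
angular or hydrogen-bond criterion. The **hydration number** uses water
*oxygens* only, cutoff 4.85 Å, no exclusion.

`consistency_check_rdf_coordination()` ties the two together: the shell-wise
integral `Σ g(r)·4πr²·ρ·δr` up to the cutoff must reproduce the directly
counted coordination number. The residual is bounded by the half-bin
discretization at the cutoff; choosing δr so the cutoff falls on a bin edge
(e.g. δr = 0.05 Å for 4.85 Å) keeps the discrepancy well under 1%.

## Order parameters

`scd_profile()` computes `S_CD = ½⟨3cos²θ − 1⟩` per chain carbon, where θ
is the angle between the segmental vector and +z, pooled over lipids of
both leaflets and frames. `S_CD` is invariant under z → −z, so leaflets
pool without sign gymnastics; the pooled value equals the
sample-count-weighted mean of per-leaflet values (asserted in tests).

The phrase "segmental vector" hides a genuine ambiguity, so both
conventions are implemented and stamped into the result:

* `CH_bond` (default): the C→H vector, averaged over all hydrogens bonded
  to the carbon. This is the standard *deuterium* order parameter for
  all-atom trajectories and the convention a SCD comparison against NMR
  implies.
* `C_neighbor`: the C(i−1)→C(i+1) vector (terminal carbons skipped), a
  common stand-in when hydrogens are absent.

Chain carbon 1 is the chain carbon bonded to the glycerol ester — atom
`C31` for sn-1, `C21` for sn-2 in the usual naming. No sign flip or
absolute value is ever applied silently; `abs = TRUE` exists for plotting
parity with conventions that display |S_CD|. Typical liquid-crystalline
profiles plateau near 0.2 and decay toward the tail, with a dip at the
sn-2 double bond; the generator's default targets follow that shape.

## Headgroup dynamics

`head_vector_raf()` computes the rotational autocorrelation of the *unit*
P→N (or As→N) vector, `RAF(t) = ⟨v̂(t₀)·v̂(t₀+t)⟩`, averaged over all lipids
and multiple time origins. The maximum lag is **half the analysis window**
and origins run over the first half, so every lag is estimated from the
same number of origins and the curve's statistical quality is uniform in t.
Unit vectors make RAF(0) = 1 exactly. The normalization is stated because
the defining expression is sometimes written without it; a dot product of
non-normalized vectors would not start at 1.

`kww_fit()` fits the stretched exponential `RAF(t) = exp(−(t/τ)^β)`,
0 < β ≤ 1, by the classical linearization: an unweighted least-squares line
of `ln(−ln RAF)` on `ln t` (t in ns). The slope is β and the t = 1 ns
intercept is −β ln τ, hence `τ = exp(−intercept/β)`. The stretched
exponential describes neither the very early nor the very late decay well,
so the fit uses the region where RAF lies within `fit_bounds` (default
[0.05, 0.95], config-exposed and stamped in the output). Numerically the
window is the **contiguous lag range between the first crossing of the
upper bound and the first crossing of the lower bound**: identical to
value-based membership for a monotone (noiseless) decay, but immune to the
selection bias that arises on noisy curves when only *upward* noise
excursions past the lower bound would re-enter the fit (pointwise selection
biases β low by ~0.1 at typical sampling). A curve that never decays into
the window (e.g. a frozen system) yields `converged = FALSE` rather than an
error, so pipelines degrade gracefully.

`tilt_statistics()` measures the angle between the unit P→N vector and the
*outward* leaflet normal (+z upper, −z lower) so the two leaflets pool
consistently; means near 70–80° say the headgroup lies nearly in the
membrane plane, pointing slightly out toward the water.

## Lateral diffusion

`msd_lateral()` builds per-lipid mass-weighted centers of mass in x,y. Two
unwrapping steps matter: atoms are first wrapped to their own lipid's
headgroup image (so a boundary-straddling lipid has a sensible COM), then
the COM track is unwrapped across frames by removing any frame-to-frame
jump exceeding half a box edge. This requires the frame spacing to be fine
enough that genuine COM motion stays below L/4 per step — comfortably true
at 5 ps spacing and lipid-scale diffusivities; a warning fires otherwise.
`MSD(t)` averages over all lipids and all origins available for each lag.

`diffusion_fit()` takes `D_xy = slope/4` of an unweighted least-squares
line over a lag window, default 10–50% of the maximum lag (skipping the
short-time regime and the origin-starved tail), and converts via
1 Å²/ns = 10⁻⁷ cm²/s. Two linearity diagnostics are attached — the fit R²
and the log-log slope α (1 diffusive, 2 ballistic) — and `nonlinear` is set
when either flags a departure (R² < 0.995 or |α − 1| > 0.2). A negative
slope is reported as a negative D with a warning and a flag, never silently
clamped.

**Sampling caveat.** At 96 lipids × 1000 frames, the MSD at the longest
fitted lags rests on a handful of independent displacement blocks per
lipid: the single-run D estimate carries an intrinsic ~10–15% scatter with
the default window, dominated by the long-lag end (the end-to-end
displacement of a 48-walker ensemble alone has ~20% relative standard
error). The package's own recovery protocol therefore averages the
estimate over three replicate realizations and fits the short-lag regime
(2–20% of the maximum lag), which is strictly linear for Brownian motion
and far better sampled; that protocol recovers the planted D to a few
percent. For real trajectories, where sub-diffusive caging makes the short
lags suspect, the default 10–50% window remains the safer general-purpose
choice — hence the asymmetry between the default and the recovery protocol.

## The synthetic bilayer generator

`generate_bilayer()` emulates the *statistical structure* the analyses
assume, not the physics. Defaults mirror a conventional bilayer study
system: 48 lipids per leaflet (96 total), 4863 water oxygens, 13 Na⁺ and
13 Cl⁻, frames every 5 ps, a lateral box sized for ~53 Å² per lipid,
leaflet separation 44.8 Å, tilt distribution (75.6°, 26.7°), lateral
diffusion 0.675 Å²/ns (the magnitude scale of measured lipid diffusivities,
~7 × 10⁻⁸ cm²/s), 16 sn-1 and 18 sn-2 carbons (palmitoyl/oleoyl). The
rotational diffusion coefficient defaults to 1 ns⁻¹ so the headgroup
relaxation completes inside the 5 ns synthetic window and the KWW fit has a
full decay to work with; real headgroup relaxation is 1–2 orders slower,
which would simply be invisible at this trajectory length.

Model components, and what each guarantees:

* **Lateral motion**: per-lipid 2-D Brownian paths with step variance
  `2·D_lateral·dt` per axis. After placing all atoms, each lipid is rigidly
  re-centered laterally so its mass-weighted COM follows the planted path
  *exactly* — otherwise the choline swing and hydrogen placement would add
  a spurious diffusive component on top of `D_lateral` and the planted
  truth would not be the truth. Box "breathing" is an AR(1) process
  (ρ = 0.99, stationary sd `box_fluct_sd`): large slow excursions, tiny
  frame-to-frame changes, mimicking a barostat — important because
  per-frame-independent box jitter would corrupt COM unwrapping at every
  boundary crossing.
* **Headgroup orientation**: with a target tilt distribution, the polar
  angle follows a reflected Ornstein–Uhlenbeck process toward the target
  mean with the target stationary sd (relaxation time `tilt_relax_ns`),
  and the azimuth diffuses at a rate set by `D_r`; the exact realized
  distribution is reported by `ground_truth_report()` rather than claimed
  analytically. With `tilt_mean_deg = NULL` the vector performs free
  isotropic diffusion on the sphere (tangent-step discretization, accurate
  for `D_r·dt ≪ 1`), for which `RAF(t) = exp(−2 D_r t)` exactly — the
  analytic anchor for relaxation-fit validation. `D_r = 0` freezes all
  orientational motion, giving the degenerate RAF ≡ 1 / MSD ≡ 0 limits.
* **Leaflet mirroring**: in the tilt-biased mode the lower leaflet mirrors
  the upper one's orientations and hydrogen azimuths (z-reflected), so the
  per-lipid COM corrections are identical across leaflets and mirrored
  pairs stay laterally registered — which is what makes the measured
  thickness equal the planted separation *exactly* at zero z-noise. The
  free-rotor mode instead gives every lipid an independent orientation
  (it exists to verify rotational statistics, where independent rotors are
  what counts).
* **Chains**: carbon k's two hydrogens are placed at the fixed polar angle
  `θ* = acos(√((2S*_k + 1)/3))` with fresh random azimuths each frame, so
  the CH-bond S_CD of carbon k is `S*_k` to floating-point precision.
  Chains are straight along the normal, so the C-neighbor convention reads
  exactly 1 on generator data — a feature for testing, not realism.
* **Hydration**: `hydration_count` water oxygens per lipid are planted at
  fixed radii inside the cutoff (re-oriented each frame, riding the
  headgroup), the rest fill the bulk slab uniformly. Infeasible packing
  (more shell waters than fit at physical water volume) is an error.
  Realized counts exceed the planted number whenever a *neighbouring*
  lipid's shell waters fall inside the cutoff; `ground_truth_report()`
  recounts the realized truth by explicit periodic-image enumeration — an
  arithmetic path independent of the analysis code — and recovery is
  asserted against that, exactly, frame by frame.
* **Salt bridges**: `bridge_count = b` is guaranteed by moving lipids in
  rigid Brownian clusters of b+1 members whose internal offsets are small
  enough that every member's choline N stays within the cutoff of every
  other member's headgroup center (the lipid count per leaflet must divide
  into such clusters). This leaves COM diffusion, tilt, order parameters,
  area and thickness untouched, but the near-coincident cluster members
  share hydration shells, so planting is **off by default**: at the default
  area per lipid the lattice geometry already yields a natural bridge count
  of 1–2, and the planted mode is switched on explicitly for
  bridge-recovery and contrast experiments.
* **Fixed-volume compression** (`lateral_compression`): shrinks the lateral
  box linearly over the run while z scales as 1/s², reproducing the
  area-thickness anti-correlation a bilayer shows when laterally
  compressed.

What the generator does **not** emulate: excluded volume (waters are
points), water structure, chain conformational dynamics (S_CD targets are
static), headgroup-water electrostatics, or any real free-energy surface.
Passing recovery tests therefore demonstrates that the *estimators* are
correct — unbiased, correctly normalized, correctly imaged — not that any
physical prediction about real bilayers is right.

## Determinism and the analysis pipeline

A spec plus seed determines the trajectory bit for bit. `run_full_analysis()`
chains all stages; every stage is a pure function of (trajectory, config),
so single-stage runs reproduce pipeline numbers identically, and a failing
stage aborts with its name while preserving completed results. Defaults:
hydration cutoff 4.85 Å, salt-bridge cutoff 6.75 Å, RDF δr 0.1 Å, density
bin 0.5 Å, KWW bounds [0.05, 0.95], MSD fit window 10–50%, analysis window
= latter half. The resolved configuration is written beside the outputs.

## Validation summary

The test suite validates along four independent routes: (i) brute-force
oracles — explicit 27-image distance enumeration, O(n²) recounts,
all-origin double loops — matched exactly on small instances; (ii) analytic
limits — S_CD ∈ {1, −0.5, 0} for aligned/in-plane/isotropic vectors,
RAF = cos(ωt) for rigid rotation, RAF = exp(−2D_r t) for free rotation,
MSD = v²t² for drift, g(r) = 1 for an ideal gas; (iii) parameter recovery
at the full 96-lipid, 1000-frame scale against the generator's
realized-truth report; (iv) internal consistency — RDF integral vs
coordination count, stage-vs-pipeline bit-identity, same-seed
reproducibility. Problem sizes were chosen so the whole suite runs in a few
minutes on one core.
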