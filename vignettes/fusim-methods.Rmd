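---
title: "fusim: models, numerics, and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fusim: models, numerics, and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fusim` simulates focused-ultrasound sonications of tissue-mimicking
gelatin/canola-oil phantoms end to end: synthetic voxel phantom →
phased-array source → hybrid angular spectrum (HAS) acoustic propagation →
power deposition → Pennes bioheat solution → comparison metrics. This
vignette documents the physical models, parameter conventions, and the
numerical choices, including the in-repo full-wave solver used to
cross-validate the HAS propagator.

## Conventions and units

All interfaces use millimetres for lengths, seconds for times, Pa for
pressure phasor amplitudes, W for acoustic powers, W/m³ for deposited power
density, and °C for temperature *rise* above baseline. The coordinate system
is right-handed with z the beam axis and the origin at the transducer face
center; grid positions refer to voxel centers.

Phasors use the engineering convention `e^{+jωt}`, so a forward-travelling
plane wave is `e^{−jkz}` and the axial spectral wavenumber branch satisfies
`Im(kz) ≤ 0` (evanescent components decay). Attenuation values are stored in
Np/cm at 1 MHz in the material table and scaled linearly with frequency
(`scale_attenuation()`), consistent with the near-linear frequency dependence
of gelatin phantoms in the hundreds-of-kHz to MHz range.

## Materials

`default_material_table()` holds water, canola oil, and gelatin at 30/50/70
milk-concentration, with speed of sound, density, attenuation at 1 MHz,
and (where on record) thermal conductivity and specific heat. The 30% and
50% gelatins are acoustic-only: their thermal entries are `NA`, accepted by
the acoustic chain and rejected by the thermal solver with a clear error.
Characteristic impedance is `Z = ρc`; the gelatin/oil impedance step gives a
pressure reflection coefficient of magnitude ≈ 0.11, which motivates the
reflection passes below.

## Synthetic phantoms

`build_cylinder_phantom()` rasterizes a host cylinder (axis along z) with
ellipsoidal oil inclusions by a voxel-center membership test; inclusions
override the host and the host overrides the water surround. `phantom_preset()`
provides three classes patterned after typical experimental phantoms: a
homogeneous 102 × 30 mm cylinder, the same cylinder with three oil
inclusions, and a 102 × 150 mm cylinder with four inclusions in its
pre-focal half. The exact inclusion geometry of any physical phantom is not
on record, so placement is a seeded random draw (semi-axes 4–8 mm, 4–5 mm in
the thin cylinder, non-overlapping, fully inside the host). The presets are
therefore *plausible* heterogeneous media for method validation, not
replicas of specific phantoms; this is the main realism limit of the
generator, together with the sharp (non-graded) material boundaries implied
by nearest-voxel rasterization.

All randomness in the package flows from one integer seed through named
substreams (`substream_seed(seed, "phantom")`, `"array-layout"`, …), so a
`run_config()` reproduces its whole artifact bundle bit-for-bit.

## Phased-array source

`make_array()` places circular elements by seeded rejection sampling inside
a rectangular aperture and projects them onto the focal sphere (default: 256
elements of 2.5 mm radius in a 144 × 98 mm aperture, 100 mm radius of
curvature, 940 kHz). `focus_phases()` sets element phases to `+k(d − F)`
where `d` is the element-to-target distance, so contributions arrive at the
target in phase under the `e^{−jkr}` propagation kernel.

`rayleigh_sommerfeld()` evaluates the Rayleigh–Sommerfeld integral

p(r) = Σ (jωρ u ΔA / 2π) · e^{−jk|r−r′|} e^{−α|r−r′|} / |r−r′|

over sub-sources laid out in a sunflower pattern on each element at ≤ λ/4
spacing (convergence is verified against the O'Neil on-axis piston solution
in the tests). The compute kernel is C++ (Rcpp, OpenMP-aware). The sampled
plane is then scaled to a prescribed acoustic power with `scale_to_power()`
using the plane-wave intensity relation `I = |p|²/2Z`; scaling refuses
beams clipped by the plane window. The refusal criterion is energetic — more
than 1% of the plane-integrated energy on the one-pixel border ring — rather
than a border-amplitude bound: sparse random arrays carry an incoherent
sidelobe floor near `1/sqrt(N)` in *amplitude* (measured up to ~13% of the
plane maximum on ordinary, physically unclipped source windows) which says
nothing about lost power, while a genuinely clipped main lobe always places
percents of the total energy on the ring (the floor contributes well under
0.5%).

## Hybrid angular spectrum propagation

`has_propagate()` marches the complex pressure plane through the voxel model
slab by slab (slab thickness = voxel size Δz). Each step applies

1. a **space factor** per voxel, `exp(−j(k(x,y) − k̄)Δz) · exp(−α(x,y)Δz)`,
   carrying the local phase advance relative to the slab-mean wavenumber k̄
   (arithmetic mean of `2πf/c` over the plane) and the local absorption, and
2. a **spectral advance** over Δz with the homogeneous propagator at k̄,
   `exp(−j kz(k̄) Δz)` with `kz = sqrt(k̄² − kt²)` on the `Im(kz) ≤ 0` branch
   (evanescent components decay by default; `"zero"` truncation optional).

In a homogeneous medium `k ≡ k̄`, the space factor reduces to pure
absorption and the method *is* the classical angular spectrum — the package
treats this reduction as an exact acceptance criterion (≤ 1e-9 relative).
Transverse FFT wrap-around is suppressed by zero padding (`pad_fraction`,
default 0.25 per side, padded up to FFT-friendly sizes) and an optional
raised-cosine edge taper on the source plane.

**Reflections.** At each axial interface the per-column pressure reflection
coefficient `R = (Z₂ − Z₁)/(Z₂ + Z₁)` splits off a backward wave. After the
forward pass, a backward sweep propagates the accumulated reflected waves
(mirror-symmetric to the forward step), and a second pass re-reflects them
forward with `−R`. The passes are summed **coherently** with the forward
field: the solver is monochromatic and steady-state, so reflected waves have
a definite phase relative to the incident field, and interference (standing
waves between interfaces) is physically real rather than noise. For a
uniform-impedance model every `R` is zero and the passes return exactly
nothing. Two passes capture first- and second-order reflections; the
neglected higher orders scale as `R³ ≈ 10⁻³` for the gelatin/oil step.

## Full-wave reference solver

`fullwave_steady_state()` solves the heterogeneous Helmholtz equation
`∇²p + k²(x)p = −s` by the convergent Born series: with
`V = k² − k₀² + iε` and the preconditioned Green's operator
`γ = −(i/ε)V`, iterate `u ← u − γ(u − G(Vu + s))`, which converges
unconditionally when `ε ≥ max|k² − k₀²|` (we use 1.05×). Absorbing layers
are realized as quadratic imaginary-`k²` ramps in the padding; the source
plane enters as a sheet source whose spectrum `2i·kz·P̂/Δz` reproduces the
prescribed plane exactly in the homogeneous limit (near-evanescent
components above 0.95k are excluded from the sheet to keep the operator
bounded). Iteration stops when the relative residual falls below `tol`
(default 2e-4, well below the few-percent discretization differences the
solver is used to measure). This solver models the full scalar wave physics
— multiple scattering, refraction at arbitrary angles, standing waves — at
the price of large padded FFTs, and serves as the independent reference for
the HAS cross-validation metric (`crossval_rmsdn()`).

The cross-validation scenario is a reduced heterogeneous model: a ~30 mm
70%-gelatin slab with one 8–10 mm oil inclusion in a 30 × 30 × 40 mm domain
at 0.25 mm, both solvers driven by the identical focused source plane, and
the normalized RMS difference (Eq. 1 form: RMS over a 41³-voxel focal
region, divided by the reference maximum over that region, no
self-normalization of either pattern) evaluated around the *reference* peak
voxel. Centering on the reference peak rather than the geometric focus
matters because the slab's sound-speed contrast shifts the focus several mm
up-beam.

## Power deposition and bioheat solution

`power_deposition()` converts the steady-state phasor magnitude to the
volumetric source `Q = α|p|²/Z` (α in Np/m). `resample_power_deposition()`
block-averages Q to a coarser thermal grid, conserving `∫Q dV`.

`pennes_fdtd()` integrates `ρc_p ∂T/∂t = ∇·(k∇T) + Q − w(T − T₀)` with
forward Euler on a 7-point stencil, harmonic-mean face conductivities at
material interfaces (the physically correct series combination for flux
continuity), and zero-flux mirror boundaries. The step straddling the end
of sonication applies Q for exactly the remaining fraction, so deposited
energy equals `∫Q dV × t_heat` to machine precision — the conservation and
adiabatic-rise acceptance tests exploit this. The explicit stability bound
`min ρc_p Δx²/(6k)` is computed by `stability_bound()` and enforced; for
70% gelatin at 0.5 mm it is 0.283 s, comfortably above the 0.1 s step used
in the study protocol. Perfusion is retained for generality and is zero in
phantom materials.

## Comparison metrics

* `rmsdn_pressure()` — Eq. 1: RMS of the difference over a focal region
  (default 41³ voxels) divided by the reference regional maximum, in %.
* `rmsd_temperature()` — Eq. 2: RMS difference in °C over a region, plus
  the normalized variant (divided by the reference maximum *rise*, which is
  the natural normalizer since fields are rises above baseline). The region
  defaults to the whole grid; for experimental comparisons a focal region
  should be passed explicitly.
* `emd()` — exact earth mover's distance between 2-D magnitude patterns via
  the transportation simplex (MODI), verified against an independent LP on
  random cases; distances stay in original pixel units even when patterns
  are binned (>64/side) for tractability.
* `fwhm()` — per-axis full width at half maximum through the field peak
  with linear interpolation of the half crossings.
* `center_of_thermal_mass()` / `delta_cotm()` — temperature-weighted
  centroid above a 1 °C threshold and displacement between two of them.
* `temperature_curves()` — mean-temperature time curves in a focal cube
  (default 16 mm³ ≈ 5×5×5 voxels of 0.5 mm — an 8× volume interpreted as a
  small averaging neighborhood around the peak voxel).
* `resample_field()` — trilinear resampling onto a coarser/finer grid for
  cross-grid comparisons (affine fields reproduce exactly; verified).

## Reproducing the cross-validation number

```{r}
# from the package root
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
library(fusim)
r <- crossval_rmsdn(seed = 1, verbose = TRUE)
r$value   # RMSDn (%) of HAS vs full wave over the 41^3 focal region
```

On one CPU this takes a few minutes (the full-wave solve dominates; ~80
Born iterations on the padded grid). The measured value is well inside the
5% acceptance bound; the residual difference is dominated by physics absent
from HAS (multiple scattering and wide-angle refraction at the oil
inclusion) plus discretization, not by solver tolerances.
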