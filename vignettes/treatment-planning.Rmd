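---
title: "Planning gold-nanorod photothermal therapy: model, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning gold-nanorod photothermal therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phototherm)
```

## The problem

Near-infrared photothermal therapy treats superficial tumors by converting
laser light into heat. At 1064 nm, skin absorbs weakly, so the tumor is
loaded with gold nanorods whose localized surface plasmon resonance raises
its absorption coefficient by orders of magnitude. The therapeutic window
is narrow: tumor tissue held between 43 and 50 °C dies by apoptosis
(self-contained, no damage to neighbors), while tissue above 50 °C
necroses — dangerous when it happens in surrounding healthy skin.
Treatment planning therefore means choosing the laser power, the
nanoparticle loading (volume fraction $f_v$), and the laser duty cycle so
that the tumor stays inside the apoptosis band as long as possible while
normal tissue stays out of harm.

`phototherm` simulates this planning problem end to end: light transport,
heat diffusion, dose metrics, and the parameter sweep that locates the
optimum.

## Geometry and materials

The phantom is a cylinder of tissue, radius 15 mm and depth 20 mm, with
four stacked skin layers (epidermis 0.08 mm, papillary dermis 0.5 mm,
reticular dermis 0.6 mm, subcutaneous fat 18.82 mm) and a squamous-cell
carcinoma modeled as a cylinder of radius 5 mm and depth 2 mm whose top
face is 0.1 mm below the surface. `skin_layers()` holds the thermal
($c_v$, $\rho$, $k$) and optical ($g$, $\mu_a$, $\mu_s$) properties of
every region; `tumor_optics_table()` the loaded-tumor optical
coefficients for $f_v \in \{10^{-3},\dots,10^{-6}\}$.

`build_phantom()` voxelizes this geometry on a Cartesian grid ($z$
downward from the surface, origin on the beam axis; each voxel owns the
half-open interval $[i d, (i+1)d)$ and takes the region containing its
center). Voxels whose centers fall outside the 15 mm radius are inactive:
photons entering them escape and no heat conducts across them.

Two resolution caveats are deliberate, documented behavior rather than
silent approximations:

* The 0.08 mm epidermis is thinner than any practical voxel, so at the
  default sweep resolutions it is represented only through the warning
  `build_phantom()` emits and, optionally, through
  `blend_surface = TRUE`, which gives surface voxels thickness-weighted
  layer averages. Blending is off by default; at 0.5–1.0 mm voxels the
  blended surface properties differ from the center-assigned ones by only
  a few percent, because the epidermis occupies at most 16 % of the
  surface voxel.
* At 1.0 mm voxels the reticular dermis (0.58–1.18 mm) can also lose its
  voxel row to center assignment. The 0.5 mm preset retains all layers
  except the epidermis.

## Nanoparticle optics

Gold nanorods (aspect ratio 6.67, effective radius $r_\mathrm{eff}$ =
20 nm) contribute
$$\mu_{a,np} = \frac{0.75\, f_v\, Q_a}{r_\mathrm{eff}}, \qquad
  \mu_{s,np} = \frac{0.75\, f_v\, Q_s}{r_\mathrm{eff}},$$
and the loaded tumor's coefficients are the sums of host and nanoparticle
terms; the anisotropy factor stays at the host value. The efficiency
factors $Q_a$, $Q_s$ are not computed electromagnetically here — they are
back-derived from the published loaded-tumor table
(`derive_efficiencies()`), either by a least-squares slope through the
origin over all four columns (default, $Q_a \approx 14.86$,
$Q_s \approx 3.14$) or from a single column. The four columns are
mutually consistent with a single $Q$ to better than 2 %, the residual
being printed rounding.

## Light transport

`trace_photons()` is a voxelized hop–drop–spin Monte Carlo transport
code. Each packet launches with unit weight uniformly over the 5 mm
top-hat beam disk at normal incidence; then repeatedly:

1. **Hop** — a dimensionless optical depth $-\ln \xi$ is consumed
   voxel-by-voxel at the local $\mu_{tot}$ (the step law
   $S = -\ln(\xi)/\mu_{tot}$ holds exactly in homogeneous regions and
   generalizes continuously across interfaces).
2. **Drop** — at the interaction the packet deposits
   $\Delta W = W \mu_a / \mu_{tot}$ in the current voxel.
3. **Spin** — the survivor deflects by a Henyey–Greenstein cosine at the
   local $g$ and a uniform azimuth, applied through the standard
   direction-cosine rotation (with its degenerate near-vertical branch).

Boundaries are matched: packets crossing the surface, the lateral or
bottom limits, or entering inactive voxels escape and are tallied
(a configurable specular fraction exists for surface reflection; default
0, since the governing equations carry no Fresnel terms). Termination is
by Russian roulette (threshold $10^{-4}$, survival probability 0.1,
survivor weight ×10), which is unbiased; the realized roulette imbalance
is tallied so that absorbed + escaped + roulette net equals the launched
weight *exactly*, not just in expectation. Randomness comes from a
dedicated xoshiro256+ stream seeded once per trace, so maps are
bit-reproducible across platforms and leave R's RNG untouched.

The output `absorption_map` stores the per-voxel *fraction* of emitted
energy absorbed. The heat source in a voxel at laser power $P$ is then
$A \cdot P / (\rho c_v V)$, which ties the fluence–absorption product to
an exactly energy-conserving discrete source.

Verification in the test suite: exact weight conservation to $10^{-9}$;
Beer–Lambert depth profiles in absorbing-only slabs; Henyey–Greenstein
first moments at $g$ = 0.75/0.8/0.9 and the isotropic limit by
Kolmogorov–Smirnov; rotation norm preservation to $10^{-12}$; and, beyond
those, a semi-infinite isotropic half-space at single-scattering albedo
0.9 reproduces the classical diffuse-reflectance value (≈ 0.41).

## Heat diffusion

`run_treatment()` integrates the heat-diffusion equation
$\partial T/\partial \tau = (q + \nabla\!\cdot\!(k \nabla T))/(\rho c_v)$
with an explicit finite-difference scheme. Face conduction uses the
harmonic-mean conductivity $2 k k_{nb}/(k + k_{nb})$, the correct
series-resistance form for material interfaces. There is deliberately no
blood-perfusion term — the governing model is pure conduction, which is a
known limitation for in-vivo extrapolation.

Choices the model statement leaves open, fixed as follows:

* **Initial / far-field temperature** 37 °C (body temperature;
  configurable).
* **Boundaries** `"semi-infinite"` (default): adiabatic at the air-facing
  surface (no convection coefficient is part of the model), fixed 37 °C
  at the lateral and bottom limits, which sit far from the heated region.
  `"adiabatic"` closes the system entirely and is used by the
  energy-budget tests.
* **Time step** auto: the explicit stability bound
  $\min \rho c_v / (2k \sum d_i^{-2})$ times a safety factor 0.5, then
  rounded down so snapshots (default every 1 s) fall exactly on step
  boundaries. Divergence (a non-finite voxel) aborts with the voxel
  location and advice to lower the safety factor.
* **Duty cycle** heating time 30 s; cooling time $\varphi_c \times$ 30 s;
  total treatment 900 s. $\varphi_c = 0$ is continuous heating.

Because properties are temperature-independent and the equation is
linear, the temperature *rise* is exactly proportional to laser power.
The tests assert this superposition to $10^{-8}$ relative, the adiabatic
energy budget (banked energy = absorbed power × on-time) to $10^{-6}$
relative, and free spreading of a point deposit against the analytic heat
kernel to 3 %.

## Dose metrics

From each temperature snapshot:

* $\theta_A$ — fraction of tumor volume inside $[43, 50)$ °C. The band is
  half-open: exactly 50 °C counts as necrotic. The denominator is the
  whole tumor volume.
* $\theta_H$ — band-weighted fraction of *normal*-tissue volume. The
  default `hazard_weighting()` is a declared stand-in (weight 0 below
  43 °C, 1 in the apoptosis band, 2 at and above 50 °C) and is a named,
  versioned object precisely so an alternative scheme can be swapped in
  without code change; the location of the effective-ratio optimum is
  sensitive to it.
* Time averages $\theta_A^*$, $\theta_H^*$ are trapezoidal means over the
  snapshot times, and
  $\theta_{eff}^* = \theta_A^*/\max(\theta_H^*, \varepsilon)$ with
  $\varepsilon = 10^{-3}$ guarding the no-hazard case. The guard matters
  structurally: at low powers $\theta_H^*$ sits below $\varepsilon$, so
  $\theta_{eff}^*$ grows like $1000\,\theta_A^*$ until hazard emerges,
  which makes the $\theta_{eff}^*$ landscape flat and guard-dominated
  near its maximum.

All three metrics are unit-tested against hand-computed ground truth on
synthetic fields from `synth_temperature_series()` — a baseline plus a
sharp-edged spherical hot spot with a prescribed temporal profile. The
generator is deterministic plumbing for tests: it emulates hot-spot
geometry only, not conduction physics, beam shape, or measurement noise,
so metric tests passing on it says nothing about transport or solver
accuracy (those have their own oracles above).

## The sweep and its shortcut

`run_sweep()` covers the full study grid — 51 powers (0–1000 mW by
20 mW), four volume fractions, six cooling ratios
$\{0, 0.5, 1, 1.5, 2, 2.33\}$, 1224 conditions — with 4 Monte Carlo
traces and 24 unit-power solves instead of 1224 solves: the unit-power
temperature excess $u$ is computed once per $(f_v, \varphi_c)$, and band
membership at power $P$ is a threshold test on $u$ (e.g. in-band means
$6/P \le u < 13/P$), accumulated in compiled code at every snapshot for
all powers simultaneously. A test verifies that a reduced sweep equals a
standalone full-power pipeline run of the same condition to $10^{-8}$.

Problem sizes: unit tests run at 1.0 mm voxels with $2\times10^4$
photons; the reproduction script and the study-level tests run at 0.5 mm
voxels with $2\times10^5$ photons per volume fraction (about two minutes
on one CPU). `fidelity_preset()` names both.

## Known limitations and observed behavior

* The model statement gives no spatial resolution or time step; results
  with sharp surface absorption (high $f_v$) retain visible grid
  dependence near the surface monitor point.
* Under the stated boundary conditions (adiabatic top, no perfusion, no
  convective sink) the simulated temperatures agree with a closed-form
  conduction estimate for a heated disk on a half-space
  ($\Delta T \sim P_{abs}/(4 k a)$, ~25–30 K at 200 mW absorbed).
  Published traces for the same nominal conditions run cooler, implying
  an additional unstated energy sink in the reference computation; at
  this package's conditions the retention-optimal powers therefore land
  ~20–30 % below the published coordinates, with the same qualitative
  structure (optimal power increasing with $\varphi_c$, lightest loading
  maximizing $\theta_A^*$).
* $\theta_H$ weights above 50 °C are a stand-in (the reference weighting
  is not published in the source at hand); the $\theta_{eff}^*$ optimum
  moves with the weighting and with $\varepsilon$.
* No polarization, refractive-index mismatch, time-resolved transport,
  temperature-dependent properties, phase change, or perfusion.

## A worked condition

```{r example, eval = FALSE}
ph <- build_phantom(voxel_size = 0.5, f_v = 1e-3)
am <- trace_photons(ph, n_photons = 2e5, seed = 1)
glance(am)

ts <- run_treatment(ph, am, treatment_schedule(phi_c = 0), power_mw = 200,
                    keep_fields = FALSE)
band_crossing_time(ts$monitors$time_s, ts$monitors$T_tumor_C, 50)
autoplot(ts)
```

For study-level questions, sweep and locate the optimum:

```{r sweep, eval = FALSE}
res <- run_sweep(voxel_size = 0.5, n_photons = 2e5, seed = 1)
find_optimum(res, "theta_A_star")
find_optimum(res, "theta_eff_star")
autoplot(res, "theta_A_star")
```
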