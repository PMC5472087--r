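---
title: "Methods: simulating magnetic confinement of beta radiation in water"
author: "magbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating magnetic confinement of beta radiation in water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`magbeta` studies how a uniform static magnetic field reshapes the dose
deposited by beta particles around a point source in water. This vignette
documents the physics model, the analysis conventions, the numerical and
design choices, and — importantly — what the simplified engine can and cannot
be expected to reproduce.

## The physical picture

An electron of kinetic energy $T$ carries momentum
$p = \sqrt{(T+m_e)^2 - m_e^2}$ (MeV/c, $m_e = 0.511$ MeV). In a uniform
field $B$ the Lorentz force wraps the component of the motion perpendicular
to the field onto a circle of gyroradius

$$ r = \frac{p_\perp}{0.29979\,B} \quad [\mathrm{mm,\ MeV/c,\ T}], $$

giving a helical path with free motion along the field axis. For a 2 MeV
electron at 3 T, $r \approx 2.7$ mm — comparable to its ~10 mm pathlength in
water — so the transverse spread of the dose is strongly curtailed while the
spread along the field is not. That asymmetry is the effect the package
quantifies: the interaction volume becomes an ellipsoid elongated along the
field, hit density rises near the source, and dose falls at the transverse
periphery.

## Transport model

The engine (`run_simulation()`, compiled in C++) is a condensed-history
Monte Carlo in the continuous-slowing-down approximation:

* **Stepping.** Each step is the smaller of `max_step` (default 0.1 mm) and
  the length over which the electron loses `max_frac_eloss` (default 2%) of
  its current kinetic energy. The step's energy loss $S(T)\,\Delta s$ is
  deposited as one *hit* at the step endpoint; one hit record per condensed
  step is the package's surrogate for the discrete interaction points a
  full-physics engine would score. Histories end below the 10 keV cutoff
  (the remaining energy is deposited locally; the residual range at 10 keV
  is ~2.5 µm) or on leaving the sphere (the escaping energy is logged, so
  per-history energy balances to 10^-6 MeV by construction).
* **Stopping power.** Møller-corrected Bethe collision stopping power with
  mean excitation energy $I = 75$ eV and $Z/A = 0.55509$ for water. The
  density-effect correction is omitted — a sub-percent effect below ~2.3 MeV
  in water — and radiative losses are not transported; both are documented
  biases, not options. The CSDA range $\int \mathrm{d}T/S(T)$ evaluates to
  11.17 mm at the Y-90 endpoint 2.28 MeV, matching the textbook ~11 mm.
* **Helical advance.** The advance over each step is the exact analytic
  helix for the current field and momentum (rotation of the perpendicular
  direction component by $\Delta s \cdot 0.29979 B / p$ about the field
  axis, with the matching chord displacement), so the stepper is exact for
  scatter-free motion at any step size; at $B = 0$ it degenerates to a
  straight line. The rotation sense is that of a negative charge.
* **Multiple scattering.** After each advance the direction is deflected by
  a Highland-width Gaussian: $\theta_0 = \frac{13.6\ \mathrm{MeV}}{\beta p}
  \sqrt{x/X_0}\,[1 + 0.038 \ln(x/X_0)]$ with $X_0 = 36.08$ g/cm² for water.
  Two conventions matter and both follow standard condensed-history
  practice. First, $\theta_0$ is the *plane-projected* RMS angle, so the
  space polar angle is sampled as Rayleigh($\theta_0$) — two independent
  Gaussian projections — with uniform azimuth. Second, inside the engine the
  logarithmic term is evaluated at the cumulative tracklength rather than
  the sub-step length (Gottschalk's prescription): evaluated per sub-step it
  makes the accumulated variance depend on the step subdivision and vanish
  for the micrometre steps that the 2% energy-loss rule produces near the
  end of a track. The exported `highland_sigma()` keeps the plain
  single-step formula. Only the Gaussian core is modelled — no
  single-scatter (Molière) tail — which biases transverse tails slightly
  short.
* **Sources.** Monoenergetic (0.5–2 MeV grid) or the yttrium-90 allowed
  beta spectrum $N(T) \propto p\,E_{tot}\,(Q-T)^2 F(Z,E)$ with
  $Q = 2.28$ MeV, daughter $Z = 40$, and the non-relativistic Fermi function
  $F = 2\pi\eta/(1 - e^{-2\pi\eta})$, $\eta = Z\alpha E_{tot}/p$, sampled by
  rejection against the analytic density (exact, no tabulation). The sampled
  mean is 0.946 MeV; the nuclide's printed mean energy is 0.93 MeV, the
  small excess being the price of the allowed-shape approximation for what
  is really a first-forbidden unique transition (whose shape factor would
  push the mean further up, which is why it is not applied).
* **Reproducibility.** Every history draws from its own splitmix64
  substream keyed by (seed, particle id), so results are bit-reproducible
  and independent of execution order or batch size.

Validation anchors for this model, computed by the test suite and the
acceptance script rather than asserted here: the CSDA range at 2.28 MeV
(~11 mm), the Y-90 spectrum mean, and the mean final radial displacement of
Y-90 electrons in water (the simulated stopping points average ~2.9 mm from
the source, against the nuclide's quoted ~2.5 mm mean penetration — a ~15%
excess consistent with the missing scattering tail and straggling).

## Analysis conventions

* **Slices and stripes.** Hits are cut into slices 0.1 mm thick spaced
  1.0 mm apart along y, and each slice is histogrammed into 0.5 mm stripes
  along x (parallel to B) and z (perpendicular). Stripe bins are half-open,
  centred on integer multiples of the width, so counts are additive and
  gap-free. Counts are raw hit counts, not energy-weighted.
* **Extents and the ellipsoid volume.** The per-axis extent is a percentile
  of the absolute coordinate of all hits; the interaction volume is
  $(4/3)\pi abc$ of the three extents. The default percentile is 99.5, not
  the maximum: the maximum is an extreme-value statistic whose seed-to-seed
  scatter is large and which, in this engine, is dominated by the rare
  nearly-scatter-free histories. Both are available via the `percentile`
  argument. The choice matters: reductions computed from lower percentiles
  are systematically larger (the confined core) and from the maximum
  systematically smaller (the diffusive tail), spanning several percentage
  points at 2–3 T.
* **Central hit enhancement.** `center_hit_ratio()` compares hit counts in
  the central 0.5 mm stripe of the y = 0 slice between a field run and the
  zero-field run. The stripe is read on the *perpendicular* axis
  ($|z| \le 0.25$, $|y| \le 0.05$ mm, any x) by default: a stripe count
  integrates the in-slice hit density over the other coordinate, and
  integrating over the compressed coordinate (z) cancels the confinement
  signal identically — a stripe read on x can only ever register the
  y-compression. Reading the stripe across the field-invariant x coordinate
  makes the count respond to the transverse concentration that the field
  actually produces. The parallel-axis stripe and a spherical central
  region remain available as options.
* **Film plane.** `score_dose_plane()` accumulates hit energy in a 0.3 mm
  slab (a nominal film sensitive-layer scale) on a 0.1 mm pixel grid with
  odd dimensions so the source projects onto a pixel centre. Film response
  is taken proportional to deposited energy; no dose-response curve or
  optical model is applied, because only geometric contour diameters are
  compared. Maps are smoothed (Gaussian, 2-pixel default, via
  `EBImage::gblur`) before contouring to stabilise the maximum against
  Monte Carlo noise; smoothing is disabled in the closed-form synthetic
  tests. The diameter at a level is the extent, through the dose maximum,
  of the region above `level * max` (outer pixel edges), at six default
  levels 0.9–0.15 of the maximum. Directly on the source plane (offset
  0 mm) the dose maximum is the singular source pixel and relative isodose
  contours collapse to the sub-millimetre scale; the informative comparisons
  are at offset 2 mm, which is where the direction checks are made.

## Study conditions and problem sizes

The reference conditions are a 15 mm water sphere, source energies 0.5, 1,
1.5, 2 MeV or the Y-90 spectrum, and fields 0–3 T along x. The package's
default grid runs 10^5 histories per cell with three seeds — volume-ratio
estimates converge well below a percentage point at that size, and the full
grid completes in minutes on one CPU; `run_matrix(n_particles = 1e6)`
reproduces the original scale when wanted. The acceptance script uses 10^5
histories × 3 seeds for the volume and hit-ratio grid, 10^5 draws for the
spectrum mean, and 10^4 histories for the mean displacement. The film study
uses four seeds (mirroring the four film repeats) at 10^5 histories.

## Known limitations

* **Hit definition.** Hits are condensed-step deposition endpoints, not
  discrete physical interactions; absolute hit counts are arbitrary (they
  scale with step control), and only ratios between runs with identical
  stepping are meaningful.
* **No secondaries.** Delta rays and bremsstrahlung deposit locally. The
  dominant dose channel below 2.3 MeV in water is collision loss, but the
  missing secondary transport removes a field-independent halo that a
  full-physics engine would score.
* **Gaussian-core scattering and no straggling.** Transverse tails are
  slightly short and all electrons of one energy share one pathlength.
  Against a full-physics Monte Carlo reference these simplifications reproduce the
  direction and ordering of the confinement effects — volume ratios
  monotone in B, stronger confinement at higher energy, perpendicular
  change exceeding parallel — while the *magnitude* of the volume reduction
  is underestimated, most visibly for 1 MeV sources (of order half the
  reference reduction at 2–3 T with the default percentile). The package
  reports what its own physics produces; it does not calibrate toward
  external values.
* **Film-plane fidelity.** The capillary wall, glass, air gaps and film
  chemistry of a physical film measurement are not modelled, so measured
  film percentages are matched only in direction, not magnitude.
* **Synthetic generators** emulate the statistical structure the analysis
  assumes (compact anisotropic clouds, unimodal dose maps), not the
  transport physics. Tests that pass on them validate the analysis stages,
  not the engine.
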