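---
title: "Magnetic force tensiometry: model, fit and companion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetic force tensiometry: model, fit and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiomag)
```

## The physical model

A multicellular spheroid loaded with superparamagnetic nanoparticles and
placed over a permanent magnet experiences a uniform body-force density
`f = M_V · grad(B)` (N/m³), where `M_V` is the magnetic moment per unit
volume of the tissue (A/m, measured by vibrating-sample magnetometry) and
`grad(B)` the field gradient (T/m). Over minutes the aggregate relaxes,
liquid-like, to an equilibrium shape set by the competition between this
body force and the tissue–medium surface tension γ. With arc length `s`
along the meridional profile, radius `x`, depth `z` below the apex, and
inclination `ϕ`, force balance gives

$$\frac{d\phi}{ds} = 2b + c\,z - \frac{\sin\phi}{x}, \qquad
  \frac{dx}{ds} = \cos\phi, \qquad \frac{dz}{ds} = \sin\phi,$$

with `b` the apex curvature and `c = f/γ` the capillary constant
(1/length²). Nothing else enters: the pair `(b, c)` fully determines the
shape. Model assumptions worth stating:

* **Equilibrium only.** The approach dynamics and any viscoelastic
  transient are outside the model; only the relaxed shape is fit.
* **Uniform force.** `grad(B)` is treated as constant over the aggregate
  height; gravity and buoyancy are neglected against the magnetic term.
* **Non-wetting contact.** The substrate is non-adhesive, so the profile
  meets it at a 180° contact angle. Contact is therefore the event
  `ϕ = π`, and the wetted face is a flat disk. This boundary condition is
  a declared choice: the contact condition is not observable in a
  side-view image at these pixel scales, and 180° is the standard
  non-wetting sessile-drop convention.
* **Orientation.** `z` increases from the apex toward the substrate, the
  direction of the body force; a sessile drop "hanging upward" against
  the magnet below.

At the apex `sin(ϕ)/x` is a removable singularity (`→ b`); the first step
away from the apex uses the series `x ≈ s`, `z ≈ b s²/2`, `ϕ ≈ b s` up to
`s₀ = 10⁻⁶` apex-curvature units.

## Integrating the shape equation

`integrate_profile()` integrates with **ϕ as the independent variable**.
For `b > 0`, `c ≥ 0` the equilibrium profile is convex, so ϕ increases
monotonically and the substrate-contact condition becomes the exact
endpoint `ϕ = π` of the integration interval rather than a root to hunt
for. Two numerical points deserve mention:

* The enclosed volume is carried as an extra state
  (`dV/dϕ = π x² sin ϕ · ds/dϕ`), so `h`, `w`, `V` come out at integrator
  accuracy (default rtol `10⁻⁹`), not at output-sampling accuracy, and
  the equator `ϕ = π/2` — which defines the width — is an output point.
* The closure point is singular in the sphere limit: as `c → 0` the
  profile closes onto the axis, `x → 0` with `sin ϕ → 0`, and the ratio
  amplifies the error carried by `x`. Two measures keep this benign: the
  closure point is umbilic, `sin(ϕ)/x → (2b + cz)/2`, and that analytic
  limit replaces the ratio below `x < 10⁻⁴/b`; and the solver integrates
  to `π − 10⁻⁶` with the last sliver covered by one explicit RK4 step
  (error `O(10⁻³⁰)`), never stepping into `ϕ > π`.

`integrate_profile_rk4()` is a deliberately independent reference: a
fixed-step classical RK4 in the native arc-length form, written in C++,
with the terminal crossing located by linear interpolation inside the
final step. Agreement between the two (default tolerance `10⁻⁶` relative
at step `10⁻⁵`) is part of the test suite. A guard arc length of `50/b`
converts pathological parameter sets into a clean non-closure error.

## The inverse fit

`fit_shape()` minimizes

$$\mathcal{L}(b, c) \;=\; \sum_{q \in \{h, w, V\}}
  \left( \frac{q_\text{pred} - q_\text{obs}}{q_\text{obs}} \right)^2$$

over `(b, c)` rescaled by the equivalent radius
`R_eq = (3V_obs/4π)^{1/3}`. Relative errors make the three observables
commensurable (they differ by six orders of magnitude in raw units);
scaling by `R_eq` puts the scaled volume at exactly `4π/3` and the scaled
parameters near 1, which is where derivative-free optimizers are happy.
Initialization evaluates a log-spaced grid of scaled `c` over
`[10⁻³, 10²]`, solving at each grid point the 1-D problem for the `b`
that reproduces the observed volume; the best grid point seeds a
Nelder–Mead refinement in log-parameters (objective reltol `10⁻¹⁰`).
The objective is cheap, smooth and two-dimensional, so this is both
robust and fast (~200–300 forward solves per fit).

**Identifiability at small flattening.** As `c̃ = c·R_eq² → 0` the shape
tends to a sphere and the objective becomes flat in `c̃`: a sphere is
consistent with *any* sufficiently large tension. Below the detection
floor `c̃ < 10⁻³` (flattening below measurement resolution at realistic
pixel scales) the fit therefore reports `gamma = NA` together with the
implied **lower bound** `γ ≥ M_V·grad(B)·R_eq²/10⁻³` rather than a
number. The flatness of the objective in this regime is itself asserted
by a test. Prolate inputs (`h > w` beyond a 2 % tolerance) are rejected
as model mismatch — the model cannot produce them for `c ≥ 0`.

`gamma_from_c()` applies `γ = M_V·grad(B)/c` with explicit unit
bookkeeping: `c` in 1/µm², force density in N/m³, γ returned in mN/m.
Volume can come from the flattened image itself (default; no second
measurement needed) or, via the generator, from incompressibility with
the molded radius `R₀` — both are exposed.

## Image extraction

`segment_aggregate()` uses a global Otsu threshold with polarity
auto-detected from the top border row (the background is above the
aggregate), keeps the largest connected component, and fills holes;
side-view tensiometer images are high-contrast dark-on-bright, so
anything more adaptive would be over-fitting. The substrate row is the
lowest populated mask row (the magnet and slide are below). Physical
lengths use pixel counts inclusive of both edge pixels; the volume sums
per-row disks of radius equal to the mean of the left/right half-widths
about the width-weighted symmetry axis. A left/right asymmetry metric is
reported as a QC value (≤ 1 % on symmetric renders). Objects touching
the lateral borders or blank images raise extraction errors rather than
propagating nonsense.

## AFM detachment force

The detachment force is the magnitude of the lowest point of the
retraction trace after baseline correction. Declared choices, since
neither the baseline model nor its window is standardized:

* The baseline (offset + slope) is fit to the **final 20 % of the
  retract segment** — at a 5 µm/s retraction the tail is guaranteed far
  from contact — and subtracted from the whole retract trace. The
  approach/dwell segments are untouched.
* Before taking the minimum, the trace is smoothed with a quadratic
  Savitzky–Golay filter (window ≈ 5 % of the retract length). The raw
  minimum of a noisy trace is biased deep by single-sample excursions;
  the quadratic filter suppresses that bias without flattening a dip
  that spans many samples. Recovery of a known 1.8 nN dip under 0.1 nN
  noise is unbiased to within 0.05 nN over 50 curves in the tests.
* Dips shallower than a noise floor of 3× the corrected raw-tail
  standard deviation count as "no detachment" and return 0.
* Sign convention: adhesion is negative in the raw trace; the reported
  detachment force is the positive magnitude.

## Wound healing and invasion

`wound_coverage()` is the definitional ratio
`coverage(t) = 1 − A(t)/A(0)`, clipped to [0, 1], computed per series
(each scratch carries its own `t = 0` reference); areas come from binary
masks (`wound_area()`) or any upstream quantification, making the
statistic pixel-scale invariant. Automatic scratch segmentation from
phase-contrast images is deliberately out of scope. `invasion_index()`
is the ratio of mean per-field invading-cell counts of a condition to
the control's; the control against itself is exactly 1 by construction.
`summarize_invasion()` reports both the pooled index and per-replicate
indices with their SEM, since panels are typically drawn as means ± SEM
over three biological replicates. Whether published coverage figures are
pooled or per-replicate means is usually unstated, so both are exposed.

## Statistics

Group comparisons use the two-sided Mann–Whitney U test: exact when
`n₁ + n₂ ≤ 12` with no ties, otherwise the normal approximation with tie
and continuity corrections (mode overridable). The exact branch is
checked against full enumeration of rank assignments for every tie-free
configuration up to `n = 8`, and the type-I error at α = 0.05 is checked
by simulation. Notched boxplot summaries use linear-interpolation
quartiles (R type 7, stated so results are bit-reproducible) and the
McGill notch `1.57·IQR/√n`; the notch formula is a convention choice —
publications state "notched boxplots" without one. Star labels map
p < 0.05, 0.01, 10⁻³, 10⁻⁴, 10⁻⁵ to one to five stars. Pairwise tests
against the control are reported **without** multiple-testing
correction, mirroring how such assay panels are reported; this is a
faithful-reporting choice, not a statistical recommendation.

## The synthetic study

`synth_study()` generates every input of the pipeline with known ground
truth, seed-deterministic throughout. The defaults encode the study
conditions the package emulates: a carcinoma line with a non-targeting
control (γ 16 ± 9 mN/m; detachment 1.8 ± 0.8 nN), two guides ablating
NME1 (γ 4 ± 3 and 7 ± 2; detachment 1.4 ± 0.5 and 1.2 ± 0.4 nN), two
ablating NME2 (γ 16 ± 5 and 13 ± 5; detachment 2.0 ± 1 and 1.9 ± 0.8 nN),
and a normal-like epithelial line (γ 45 ± 18 mN/m); molded spheroid
radius 450 ± 70 µm; magnet gradient 170 T/m at ≈ 530 mT; wound coverage
targets of 55 % (control/NME2-like) versus ~78 % (NME1-like) at 24 h and
90 %/100 % at 48 h; control invasion of ~10 cells per field with a
6.5-fold increase for NME1-like conditions. Sample sizes follow the same
study: 12 aggregates per condition (the reported range is 9–15), 45 AFM
curves, 30 scratches, 5 fields × 3 replicates. `M_V` is never printed in
such studies (it is a magnetometry input), so the generator uses a
synthetic 500 A/m, chosen once so that `c·R₀² ≈ 1` at the control
tension — visible but not extreme flattening.

Distributional choices are equally explicit: tensions and detachment
forces are normal, truncated at a small positive floor; invasion counts
are Poisson; wound edges are jittered rectangles with multiplicative
noise on realized coverage. Tension "measurements" apply 1 %
multiplicative noise to `(h, w, V)` from the forward model; rendered
images add Gaussian blur and pixel noise.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: uneven illumination, debris and magnet
reflections in the field of view, partial wetting of imperfect
anti-adhesive slides, heterogeneous nanoparticle loading (per-cell `M_V`
variation), aggregate asymmetry, and correlated (non-white) AFM noise
such as drift steps. On real images the region-of-interest cropping and
the calibration accuracy of `M_V·grad(B)` will usually dominate the
error budget, not the fit.

## Problem sizes and runtime

The test suite runs the inverse fit a few hundred times (a 5×5 noiseless
recovery grid, 100 noisy replicates, a six-condition study with 12
aggregates per condition); one fit costs ~200–300 forward solves at
rtol 10⁻⁹ and runs in roughly half a second. The RK4 reference uses a
10⁻⁵ step. These sizes were chosen to exercise every code path at full
accuracy while keeping a complete run in minutes on one core.

## Known limitations

* Only equilibrium shapes: no viscosity or relaxation constants from the
  flattening dynamics.
* The 180° contact assumption is untested against partially wetting
  substrates; a finite contact angle would bias `h` low and γ
  accordingly.
* The approximate Mann–Whitney branch is conservative for very small
  samples with heavy ties.
* `fit_shape()` assumes a single aggregate per image and axisymmetry;
  strongly tilted or fused aggregates should be excluded upstream.
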