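---
title: "Quantifying bioprinted shape fidelity: models, metrics and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bioprinted shape fidelity: models, metrics and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioprintfidelity)
```

# The problem

Extrusion-bioprinted hydrogel structures (alginate, alginate–gelatin) tend
to lose their designed geometry after deposition: a filament printed across
a gap sags under its own weight, and a low-viscosity ink spreads and closes
the pores of a printed grid. This package implements the quantitative side
of a shape-fidelity assessment workflow for such constructs:

1. a mechanical model of the hanging filament, with inverse estimation of
   the ink's Young's modulus from observed sag;
2. image metrics for the filament collapse test (deflection angles θ1/θ2,
   diameter, time-to-flat, diameter-shrink slope);
3. pore segmentation and the *normalized pore number* for printed grids;
4. live/dead fluorescence spot counting for cell viability;
5. one-way ANOVA and paired t utilities; and
6. seed-deterministic synthetic fixture generators that emulate all three
   image classes with analytic ground truth, so every pipeline is testable
   without laboratory data.

# The filament collapse model

A filament of radius $r$ and density $\rho$ suspended across a gap $L$
between two pillars is modelled as a simply supported Euler–Bernoulli beam
with an axial tension $P$ (the "transfer loading" exerted by adjacent
material) and a uniform transverse load $q = \rho g \pi r^2$ from
self-weight. With no oscillation (quasi-static deformation), the governing
equation is

$$ w''''(x) - \frac{P}{EI}\,w''(x) = \frac{q}{EI}, \qquad
   I = \frac{\pi r^4}{4}, $$

with $w(0)=w(L)=0$ and $w''(0)=w''(L)=0$. The general solution is

$$ w(x) = c_1 + c_2 x + c_3 e^{kx} + c_4 e^{-kx} - \frac{q}{2P}x^2,
   \qquad k = \sqrt{P/EI}, $$

and `solve_coefficients()` returns the four coefficients satisfying the
boundary conditions. Maximum sag occurs at midspan, $x = L/2$.

## Numerical design choices

* **Basis.** The exponential pair is carried internally in a cosh/sinh
  basis centred at $L/2$; this is symmetric and avoids $e^{kL}$ overflow
  for strongly tensioned filaments. The $c_3, c_4$ of the exponential form
  are recovered by back-transformation for reporting.
* **Small tension.** As $P \to 0$ the particular solution $-qx^2/2P$
  diverges and the closed form suffers catastrophic cancellation. For
  $kL < 2$ the profile is evaluated through the cancellation-free identity
  $w = \frac{q}{Pk^2\cosh m}\left[h(ku) - h(m) + \tfrac{m^2-(ku)^2}{2}
  (\cosh m - 1)\right]$ with $h(t) = \cosh t - 1 - t^2/2$ (series-expanded
  below $t = 0.1$) and $m = kL/2$, $u = x - L/2$. This keeps the closed
  form accurate to ~$10^{-7}$ relative even at $kL = 10^{-3}$.
* **Dispatch.** The high-level constructor `beam_solution()` switches to
  the classic untensioned limit $w_{max} = 5qL^4/384EI$ below
  $kL = 10^{-2}$ and records `mode = "classic_limit"`; at the switch point
  the branches agree to a few parts in $10^5$.
* **Oracle.** `solve_deflection_numeric()` is an independent second-order
  finite-difference solution of the same boundary-value problem (ghost
  nodes enforce $w'' = 0$), standing in at desk scale for solid-model FEA.
  The closed form and the oracle agree to better than $10^{-4}$ relative
  across a random parameter sweep.

## The transfer loading P

$P$ is not identifiable from a single-filament experiment (there is no
adjacent beam), and no value is reported for it in the source workflow. It
is therefore an explicit, required parameter: the CLI default chooses $P$
such that $kL \approx 1$ for the nominal 4 mm gap and 0.4 mm radius, and
every output records the $P$ used. Making the unidentifiable parameter
visible was preferred to hiding a guess.

## Inverse modulus estimation

$w_{max}(E)$ is strictly decreasing, so `estimate_modulus()` finds the
unique root of $w_{max}(E) = w_{obs}$ by bisection on $\log_{10} E$
(relative tolerance $10^{-6}$, default bracket 10 Pa–10 MPa, spanning soft
hydrogels with margin). Round-trip recovery is exact to well below 0.1%.

**Angles versus midspan sag.** The experiment measures the two support
angles, not the midspan deflection directly. The obvious chord conversion
$w_{max} \approx \frac{L}{2}\tan\frac{\theta_1+\theta_2}{2}$
(`angles_to_midpoint_deflection()`) systematically *overestimates* the true
midspan sag of the curved profile — in the $P \to 0$ limit the support
slope is $qL^3/24EI$, giving a chord estimate of $qL^4/48EI$ against a true
$5qL^4/384EI$, a factor of $8/5$. Inverting $w_{max}(E)$ against a
chord-derived observation would therefore bias $E$ downward by tens of
percent. The image pipeline instead inverts through the angle observable
itself: `estimate_modulus_from_angles()` applies the *same* windowed
tangent-fit operator to the model profile that
`measure_deflection_angles()` applies to the segmented image, and matches
the two. This measurement-consistent inversion recovers the generating
modulus of rendered fixtures to within a few percent; the chord value is
still recorded as metadata (`w_obs`) because it is the field's conventional
summary. Drying filaments thin over time, and re-estimating $E$ per frame
against the shrinking radius yields the expected negative modulus-radius
trend, summarised by `fit_modulus_vs_radius()` (ordinary least squares with
$R^2$).

# Filament image metrics

`segment_filament()` thresholds by Otsu's method (red-dyed filaments image
dark on a bright background; RGB input is reduced to a red-minus-green
contrast channel; polarity is a flag) and keeps the largest 8-connected
component, which must span at least half the image width. The midline is
the column-wise centroid of the mask. Choices the source workflow leaves
open, and how they are fixed here:

* **Angle read-out**: straight-line fit to the midline over the first/last
  10% of the span (minimum 10 px) — a tangent-at-support estimate matching
  the published measurement schematic. Noise-free fixtures are recovered
  within 1°.
* **Diameter**: vertical mask extent at the requested span fraction,
  multiplied by the cosine of the local midline slope to obtain the
  perpendicular thickness. Accurate to one pixel on fixtures.
* **Flat threshold**: "angle reached 0°" is operationalised as the first
  linear-interpolated crossing below 0.5° (pixel quantisation makes exact
  zero unattainable); the threshold is recorded in outputs. Never-flattening
  series return an `NA` sentinel.
* **Units**: input times are seconds, reported collapse times minutes, and
  the diameter-shrink slope mm/min as a positive magnitude — the units the
  published figures use (the source leaves the slope unit implicit; mm/min
  is this package's documented assumption).

# Grid pore analysis

`segment_pores()` thresholds the grid material (Otsu), closes 1-px gaps
with a 3×3 morphological closing, takes the largest 8-connected foreground
component as the scaffold, and labels 4-connected background openings;
openings connected to the image border are the outside world and are
excluded. `match_pores_to_grid()` registers the designed lattice to the
scaffold's bounding box (which spans `span + line_width` mm — a
deterministic registration, since no registration procedure is published)
and classifies every designed cell:

* **ok** — exactly one opening's centroid in the cell, extending into no
  other cell;
* **merged** — the opening spans ≥ 2 cells (all spanned cells are marked);
* **missing** — no opening. A deliberately filled cell is indistinguishable
  from a missing one in the image, so analyzer output never contains the
  generator's `filled` state; metrics count `ok` only, so this does not
  affect them.

"Successfully printed pore" has no published operational definition; the
above classification plus a speck floor (openings below 5% of the analytic
cell area $(\text{pitch} - \text{line width})^2$ are ignored) is this
package's definition, chosen because it reproduces the designed pore count
exactly on ideal renderings and degrades correctly on every controlled
defect. The *normalized pore number* is $100 \cdot n_{ok} / n_{designed}$;
pore areas are reported in mm² via the calibration, as mean ± sample SD
over ok pores (an SD across replicate prints, the other reading of the
published error bars, can be formed by pooling per-image results).

# Viability quantification

`z_project_max()` collapses each channel of a six-plane stack by per-pixel
maximum. `find_maxima()` reimplements the ImageJ "Find Maxima" prominence
semantics: an 8-connected equal-value plateau with no higher neighbour and
at least one strictly lower one is a candidate, and it is rejected exactly
when some path to a strictly higher pixel never drops below
`peak − noise_tolerance` (default tolerance 20, applied on the raw stored
integer scale; 16-bit data are not rescaled). Plateaus are reported as
their rounded centroid; edge maxima are not excluded; no smoothing or
background subtraction is applied — all of these mirror the tool's
defaults, are configuration-visible, and are covered by an independent
path-prominence oracle in the test suite. One consequence worth knowing:
the global maximum of a channel is always reported, so an all-noise image
counts one spot, exactly as the original tool does.

Green-channel maxima are live cells (Calcein), red-channel maxima dead
cells (EthD); viability is $100 \cdot \text{live}/(\text{live}+\text{dead})$
per image, with an `NA` sentinel when nothing is counted. Across images the
mean viability is *pooled* — total live over total cells — not the mean of
per-image percentages. Maxima were originally also computed per z-position;
since the stated viability computation uses the projection, the projection
path is primary here and per-plane counts are an optional diagnostic
(`count_live_dead(..., per_plane = TRUE)`).

# Synthetic fixtures: the stated world

The generators emulate the three experimental image classes with analytic
ground truth (never measured from the rendering):

* **Filament series** (`make_filament_series()`): gaps 1/2/4/8/16 mm,
  density 1026 kg/m³ (4% alginate), calibration 45 px/mm, and a radius that
  shrinks linearly in time — the published diameter decay is near-linear —
  at a configurable rate. The default radius rate of 0.014 mm/min equals a
  diameter slope of 0.028 mm/min, the published incubator-temperature value
  for the low-concentration ink; room-temperature regimes are emulated with
  a lower rate. Each frame
  is re-solved quasi-statically; truth records the analytic midspan sag and
  support tangent angle.
* **Grid images** (`make_grid_image()`): the 20 × 20 mm, 11 × 11 = 121-pore
  design by default, with exact defect injection (merge / fill / spread)
  and anti-aliased 8-bit rendering.
* **Z-stacks** (`make_zstack()`): Gaussian spots (σ = 2 px, amplitude 200)
  placed by rejection sampling with 12 px minimum separation, assigned one
  of six focal planes over 100 µm with defocus attenuation so the max
  projection recovers the full amplitude, plus Gaussian (default σ = 4,
  i.e. 50:1 peak SNR) or Poisson pixel noise.

What a green test establishes — and what it does not: fixtures validate the
*computational* pipeline (segmentation, measurement, inversion, counting)
against known truth. They do not emulate uneven illumination, optical PSF
blur beyond a Gaussian spot, out-of-focus haze, stain bleed-through,
filament surface texture, or camera distortion, so field performance on
real micrographs still depends on imaging quality. Headline experimental
numbers from the originating study (98% normalized pore number for 3%
gelatin, >90% day-5 viability, ~6 min time-to-flat at 37 °C, the
modulus-radius $R^2 = 0.99$) depend on lab images that were never deposited
and are therefore *directional anchors*, not reproduction targets, for this
package.

# Statistics

`anova_single_factor()` and `paired_t_test()` are computed from sums of
squares / paired differences with exact F and t reference distributions
(upper-tail for F, two-sided for t — spreadsheet conventions). They agree
with R's `oneway.test(var.equal = TRUE)` and `t.test(paired = TRUE)` to
$10^{-10}$ on randomised suites. The paired statistic uses differences
`a − b` of the arguments in the order given, so its sign follows the
argument order; the magnitude and p-value do not.

# Known limitations

* Linear beam theory: sag magnitudes comparable to the span (soft inks on
  wide gaps) violate small-deflection assumptions; the model is then a
  comparative index, not a prediction.
* $P$ is unidentifiable from single-filament data and must be configured.
* Viscoelastic/creep behaviour, surface tension and Marangoni effects, and
  dynamic (vibrating) solutions are out of scope.
* I/O is text-only (ASCII PGM, a self-describing ASCII stack format, CSV,
  JSON); binary TIFF/PNG ingestion is intentionally not included in this
  build, and all analyzers operate on in-memory arrays so an external
  converter can be used.
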