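# bioprintfidelity

Quantitative shape-fidelity assessment for extrusion-bioprinted hydrogel
constructs (alginate and alginate–gelatin bioinks), for bioink developers
who need reproducible numbers instead of visual judgement.

Extrusion-printed structures degrade in two characteristic ways: a filament
suspended across a gap **sags** under its own weight, and a low-viscosity
ink **spreads**, closing the pores of a printed grid. This package turns
both failure modes — plus the accompanying live/dead biocompatibility
check — into computed quantities:

* **Filament collapse model.** A simply supported Euler–Bernoulli beam with
  axial tension *P* and self-weight load *q = ρgπr²*:

  ```
  w''''(x) − (P/EI) w''(x) = q/EI,   w(0)=w(L)=0,  w''(0)=w''(L)=0
  w(x) = c1 + c2 x + c3 e^{kx} + c4 e^{−kx} − q x²/(2P),  k = √(P/EI)
  ```

  Closed-form solver (overflow-safe, with a numerically exact P→0 limit
  `5qL⁴/384EI`), an independent finite-difference oracle, inverse Young's
  modulus estimation by bisection (`w_max(E)` is strictly decreasing), and
  the modulus-vs-radius regression.
* **Filament image metrics.** Segmentation of side-view frames, deflection
  angles θ1/θ2 at the supports, perpendicular diameter, time for the
  angles to flatten (minutes), and the diameter-shrink slope (mm/min).
* **Grid pore analysis.** Pore segmentation of top-view grid images,
  registration to the designed lattice (default 20 × 20 mm, 11 × 11 = 121
  pores), per-pore ok/merged/missing classification, the **normalized pore
  number** (% of designed pores realised) and pore-area statistics in mm².
* **Viability.** Per-channel maximum z-projection, an ImageJ-style
  find-maxima spot detector (noise tolerance 20, path-prominence
  semantics, oracle-tested), live/dead counts, per-image viability
  `100·live/(live+dead)` and pooled viability across images.
* **Statistics.** Single-factor ANOVA and the paired two-sample t-test,
  verified to 1e-10 against R's reference implementations.
* **Synthetic fixtures.** Seed-deterministic generators for all three image
  classes with *analytic* ground truth (sagging-filament series, grid
  images with controlled merge/fill/spread defects, two-channel z-stacks),
  so the entire pipeline is testable offline.

I/O is deliberately text-only: ASCII PGM images, a self-describing ASCII
stack format (`PSTACK`), CSV and JSON. Pixel calibration defaults to
45 px/mm (so a 2 px printer repeatability is the familiar ±44 µm).

## Worked example

```r
library(bioprintfidelity)

## Grid fidelity: render the 121-pore design with two controlled defects,
## then measure it back
spec <- grid_spec(span = 20, cells_per_side = 11, line_width = 0.4,
                  calibration = 45)
g <- make_grid_image(spec, defects = list(
  list(type = "merge", a = c(3, 4), b = c(3, 5)),   # wall knocked out
  list(type = "fill",  cell = c(7, 7))))            # pore closed by spread
gm <- grid_metrics(g$image, spec)
gm$normalized_pore_number   # 97.52  (% of 121 designed pores printed ok:
                            #         118 ok, 2 merged, 1 missing)
gm$mean_pore_area           # 2.011  (mm^2; analytic open cell is
                            #         (20/11 - 0.4)^2 = 2.011 mm^2)
gm$sd_pore_area             # 0.017  (mm^2, pixelisation scatter)

## Filament collapse: render a sagging filament (E = 10 kPa, 8 mm gap),
## measure its support angles, and invert the beam model
E_true <- 1e4
P <- E_true * pi * (4e-4)^4 / 4 / (8e-3)^2          # tension with kL = 1
s <- make_filament_series(E_true, P = P, gaps = 8, n_frames = 3,
                          frame_interval = 120)
fm  <- segment_filament(s$gap_8$frames[[1]], 45, supports = c(45, 9 * 45))
ang <- measure_deflection_angles(fm)
ang                         # theta1 = 25.31, theta2 = 25.42 degrees
                            # (analytic support tangent: 26.01)
p <- beam_parameters(E = 1, P = P, r = 4e-4, rho = 1026, L = 8e-3)
                            # placeholder E; the inversion ignores it
est <- estimate_modulus_from_angles(ang[1], ang[2], p)
est$E_hat                   # 10125  (Pa; 1.3% from the generating 10 kPa)

## Viability: 90 live + 10 dead synthetic spots, counted back exactly
z  <- make_zstack(n_live = 90, n_dead = 10, seed = 7)
ct <- count_live_dead(z$stack)       # live 90, dead 10
viability_percent(ct$live, ct$dead)  # 90

## Statistics
anova_single_factor(list(c(1, 2, 3), c(2, 3, 4)))$statistic   # 1.5
```

(The numbers in comments are the values these calls print; the filament
ones vary by a pixel-level amount if you change calibration or geometry.)

A command-line interface covers the same pipelines
(`beamfit`, `filament`, `grid`, `viability`, `simulate`, `stats`):

```sh
Rscript inst/scripts/bioprintfidelity simulate grid --seed 3 --out-dir out/
Rscript inst/scripts/bioprintfidelity grid --image out/grid.pgm --out-dir out/
```

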