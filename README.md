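# gelrehyd

Rehydration analysis and pore-scale capillary-filling simulation for dried
biopolymer gels, motivated by soy protein isolate / konjac glucomannan
(SPI/KGM) composite gels.

Dried plant-protein gels rehydrate slowly and unevenly, which limits their
use in instant foods. Quantifying rehydration takes three complementary
views, all implemented here:

* **Kinetics** — the moisture ratio `MC = (Wt − W0)/W0` (g water per g dry
  matter) as a function of immersion time, fit by the first-order
  (`(M−Me)/(M0−Me) = e^{−kt}`), Peleg (`M = M0 + t/(K1 + K2 t)`) and
  Weibull (`(M−Me)/(M0−Me) = e^{−(t/a)^β}`) models, compared by R² and
  SSE, plus water-holding capacity after centrifugation
  (`100·m_after/m_before`).
* **Water states** — low-field NMR CPMG decays inverted into a
  non-negative T2 spectrum (regularised NNLS) and partitioned into bound
  (0.64–6.87 ms), immobilised (6.87–204.91 ms) and free (204.91–714.94 ms)
  water populations.
* **Mechanism** — an axisymmetric two-phase incompressible Navier–Stokes
  solver with a conservative level-set interface, continuum surface
  tension `σκδn`, wetted-wall contact angle and Navier slip, simulating
  capillary invasion of water into a single air-filled gel pore above a
  reservoir. Closed-form oracles (Young–Laplace `2σcosθ/R`, Jurin height
  `2σcosθ/(ρgR)`, Lucas–Washburn `z = √(σRcosθ·t/2μ)`) validate the
  solver.

A seeded synthetic-data generator emulates rehydration curves, CPMG decays
and SEM pore-size statistics, so the whole pipeline is testable without
laboratory data.

## Worked example

Fit synthetic Weibull rehydration data and inspect the fit:

```r
library(gelrehyd)

spec <- curve_spec("weibull", params = list(a = 20, beta = 0.8),
                   M0 = 0, Me = 6.5, noise_sd = 0)
curve <- gen_rehydration_curve(spec)
fit <- fit_kinetics(curve, "weibull")
fit
#> Kinetic fit: weibull model (converged)
#>   params: a = 20, beta = 0.8, Me = 6.5
#>   M0 = 0 g/g, Me = 6.5 g/g
#>   R^2 = 1.000000, SSE = 1.972e-31 (6 iterations)
```

The scale parameter `a` is the time to 63.2% (`1 − e⁻¹`) of the total
moisture change — here 20 min — and `Me = 6.5` g/g is the equilibrium
uptake. With measurement noise (`noise_sd = 0.05`) the same round trip
recovers `a` and `β` with a median bias under 1% across seeds.

Classify water populations from a synthetic CPMG decay:

```r
decay <- gen_cpmg_decay(decay_spec(noise_sd = 0))
pops <- classify_water_populations(
  invert_cpmg(decay, t2_grid = default_t2_grid(256), reg_lambda = 0))
pops
#> Water populations (T2 windows in ms):
#>   bound        [  0.64,   6.87]: area     1.9842  peak T2 2.15 ms
#>   immobilized  [  6.87, 204.91]: area   772.0300  peak T2 44.50 ms
#>   free         [204.91, 714.94]: area    66.0070  peak T2 332.91 ms
#>   unclassified: 0.0000 of total 840.0212
```

Simulate capillary filling of a 69.11 µm pore (400 µm long, 2 µm grid,
water/air at 25 °C, contact angle 70°) — a few minutes on one core:

```r
dom <- build_domain(69.11, 400, h_um = 2)
res <- run_capillary_filling(dom, fluid_pair(), t_end_s = 1.5e-3)
res$fill_time_s * 1e3   # ms until the pore is fully covered
#> [1] 0.5526
```

The pore fills in ~0.55 ms; smaller pores fill faster (41.67 µm beats
69.11 µm beats 73.39 µm at every matched time), and the interface pressure
jump at 0.2 ms ranges from ~590 Pa (73.39 µm) to ~1120 Pa (41.67 µm),
consistent with the Young–Laplace scale `2σcosθ/R`.

Quick closed-form checks from the shell:

```sh
exec/gelrehyd oracle young-laplace --radius-um 69.11 --contact-angle 0
# 2083.63 Pa
exec/gelrehyd oracle jurin --radius-um 69.11
# 72.8633 mm
```

The same front end exposes `simulate`, `fit-kinetics`, `invert-t2` and
`synth` subcommands; every run writes a JSON manifest with its
configuration and seed.

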