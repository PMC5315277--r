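# dustballast

Quantitative analysis of dust-seeding minicosm experiments on abiotic
organic-carbon export — the pathway where Saharan dust deposited on
seawater triggers the formation of transparent exopolymer particles (TEP),
TEP glue organic matter to the mineral grains, and the resulting
organic–mineral aggregates sink, exporting particulate organic carbon
(POC) by *lithogenic ballasting*.

The package is written for marine biogeochemists working with two kinds of
tables:

* **TEP enumeration tables** — per-sample microscopy counts classified into
  logarithmic size classes (by default 15 classes between 1 and 135 µm);
* **sediment-trap composition tables** — weight percentages of total
  carbon, calcium and aluminium plus the trap aluminium mass.

All user-facing functions take a data frame first and return a tibble, so
stages chain with the pipe.

## The models

**TEP number size distribution.** Counts standardized by class width give
the size spectrum, fitted as a power law

> dN/d(dp) = k · dpᵟ

by ordinary least squares in log₁₀–log₁₀ space over positive-count classes.
The spectral slope δ measures the relative abundance of small versus large
particles. The same count table yields the abundance-weighted mean diameter
D_av = Σᵢ N(dpᵢ) dpᵢ / Σᵢ N(dpᵢ) and the volume concentration
C_v = Σᵢ (π/6) dpᵢ³ N(dpᵢ) · 10⁻⁶ (ppm). Total abundance carries a
conservative 20 % counting error.

**Sediment-trap mass budget.** Assuming trap calcium is carried by calcite,
%PIC = %Ca × 12/40 and %POC = %TC − %PIC. POC stocks become fluxes through
the minicosm geometry (0.36 m², 6 days), and aluminium is the lithogenic
tracer: dust mass in the trap = Al mass / 0.0412, the analog's Al fraction.

**Ballast regression.** Across trap budgets the POC flux is proportional to
the lithogenic flux; the zero-intercept least-squares slope
(Σxy/Σx², POC per unit lithogenic mass) extrapolates the POC export any
dust deposition event would drive.

## Worked example

Simulate a post-seeding TEP time series and summarize each sample:

```r
library(dustballast)

grid <- build_size_grid()                       # 15 log classes, 1-135 um
counts <- simulate_tep_timeseries(grid, seed = 42)
tep_summary(counts, grid)
#> # A tibble: 8 × 9
#>   sample_id abundance abundance_sd delta      k r_squared n_bins_used d_av_um cv_ppm
#> 1 T1            8112.        1622. -2.00  8409.     1.000          15    5.02 39.8
#> 2 T6           14555.        2911. -2.43 21654.     1.000          15    2.99 15.8
#> 3 T12          17119.        3424. -2.60 28434.     1.000          15    2.59 10.5
#> ...
#> 8 T144          3559.         712. -3.26  8969.     0.998          15    1.88  0.244
```

Abundance peaks in the first hours after seeding (here ~1.4–1.7 × 10⁴
TEP mL⁻¹, ± the 20 % counting SD) and then declines as aggregates settle;
δ steepens from −2.0 towards −3.3 and the mean diameter drops from ~5 to
~2 µm: the large, freshly formed TEP disappear into sinking aggregates.

Fit the ballast regression over the six published minicosm trap budgets
(three seasonal experiments × two pH treatments) and extrapolate:

```r
fit <- fit_ballast(chipie_flux_points())
fit
#> Zero-intercept ballast regression: POC flux = slope * lithogenic flux
#>   slope:   0.01235 (SE 0.00021, t = 58.60, p = 2.7e-08, df = 5)
#>   r^2:     0.984 (centered convention)
#>   points:  6

predict_poc_litho(fit, 22 * 1000) / 1000   # 22 g m-2 extreme dust event
#> [1] 0.2716949                             # ~0.27 g m-2 POC_litho
contribution_fraction(0.2717, 0.8)
#> [1] 33.96                                 # ~34% of the event POC export
```

So roughly 12 mg of organic carbon are exported per gram of lithogenic
material reaching the trap; a 22 g m⁻² Saharan event would drive
~0.27 g m⁻² of ballast-associated POC export — about a third of the export
observed after such an event, but only ~6 % of the annual carbon export at
the regional time-series station (11.4 g m⁻² yr⁻¹ dust vs 2.4 g m⁻² yr⁻¹
POC).

The full published-table reproduction (every derived budget cell, the fit
and the extrapolations) is one call:

```r
reproduce_study()
#> CHIPIE reproduction report
#>   budget cells within tolerance: 24 / 24
#>   max relative error: 0.0055
#>   ballast slope 0.01235, r^2 0.9843, p 2.7e-08
#>   event-scale POC_litho 0.27 g m^-2 (34% of export); annual contribution ~6%
```

## Package tour

| area | functions |
|---|---|
| size spectrum | `build_size_grid()`, `normalized_distribution()`, `fit_spectral_slope()`, `average_diameter()`, `volume_concentration()`, `abundance_with_error()`, `tep_summary()`, `plot_size_spectrum()` |
| trap budget | `dust_analog()`, `minicosm()`, `pic_percent()`, `poc_percent()`, `poc_flux()`, `dust_recovery()`, `lithogenic_flux()`, `trap_budget()` |
| ballast model | `fit_ballast()` (+ `tidy()`, `glance()`, `predict()`, `autoplot()`), `predict_poc_litho()`, `contribution_fraction()` |
| simulators | `simulate_tep_counts()`, `simulate_tep_timeseries()`, `simulate_trap()`, `size_class_probabilities()` |
| reproduction & pipeline | `chipie_budget_inputs()`, `chipie_printed()`, `chipie_flux_points()`, `dune_reference()`, `reproduce_study()`, `run_pipeline()` |

The methods vignette (`vignettes/dust-ballast-methods.Rmd`) documents the
statistical conventions (mid-point definition, zero-count handling, the
through-origin r², the Al-proxy closure) and what the synthetic generators
do and do not emulate.
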