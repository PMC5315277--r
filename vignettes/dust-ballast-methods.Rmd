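---
title: "Methods: TEP size spectra, trap budgets and the lithogenic-ballast regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TEP size spectra, trap budgets and the lithogenic-ballast regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustballast)
```

dustballast implements the quantitative chain of a dust-seeding minicosm
study of abiotic carbon export: dust deposited on filtered seawater triggers
the assembly of transparent exopolymer particles (TEP) from dissolved
precursors, TEP glue organic matter onto the mineral grains, and the
aggregates settle into a sediment trap. Three measurement streams feed the
chain — TEP counts binned by size, trap elemental compositions, and the
regression linking the organic and mineral fluxes — and this vignette
records the statistical conventions each one uses, why, and what the
accompanying simulators do and do not emulate.

## 1. The TEP number size distribution

TEP are counted by microscopy and classified into logarithmic size classes;
the default grid is 15 classes between `d_min = 1` and `d_max = 135` µm, so
consecutive class boundaries share the ratio $(135/1)^{1/15} \approx 1.387$.
The count of class $i$, standardized by the class width, estimates the
number size distribution, modeled as a power law,

$$\frac{dN}{d(d_p)} = k \, d_p^{\delta},$$

with $d_p$ the projected spherical-equivalent diameter (µm), $N$ in
\# mL^-1^, $k$ a concentration-dependent normalization, and $\delta < 0$
the spectral slope: the more negative $\delta$, the more the spectrum is
dominated by small particles.

**Fitting.** $\hat\delta$ and $\hat k$ come from unweighted ordinary least
squares of $\log_{10} (dN/d(d_p))$ on $\log_{10} d_p$ using the class
mid-point diameters. Three conventions are fixed here:

* *Mid-point.* "Mid-point diameter" is read as the arithmetic mean of the
  class boundaries — the plainest reading of the term. Because the grid is
  geometric, the arithmetic mid-point is exactly proportional to the lower
  boundary in every class, so a perfect power law in diameter is also a
  perfect power law in the mid-points and the fit is not biased by the
  choice. The geometric mean (`midpoint = "geometric"` in
  `build_size_grid()`) is offered because log-binned spectra are often
  paired with it; it only shifts $\hat k$, not $\hat\delta$, for the same
  reason.
* *Zero counts.* Classes with zero counts are excluded from the fit
  ($\log 0$ is undefined) and no pseudo-count is added — minimal
  intervention, recorded per sample in `n_bins_used`. Fewer than two
  positive classes is an error (`dustballast_fit_error`), never a
  degenerate fit.
* *Weighting.* The fit is unweighted; nothing in the measurement protocol
  motivates a particular variance model for log-counts, and the unweighted
  fit is the field's default.

The package's $r^2$ of the slope fit is computed directly from the log-space
residuals (not via `summary.lm()`, which warns on noise-free perfect fits —
a legitimate input here, used by the exact-recovery tests).

**Derived statistics.** From the same table: total abundance
$[\mathrm{TEP}] = \sum_i N(d_{p,i})$; the abundance-weighted mean diameter
$D_{av} = \sum_i N_i d_{p,i} / \sum_i N_i$ (always inside the mid-point
range); and the volume concentration
$C_v = \sum_i \frac{\pi}{6} d_{p,i}^3 N_i \times 10^{-6}$ in ppm (v/v),
treating particles as spheres at the class mid-point (1 µm³ mL⁻¹ =
10⁻¹² v/v).

**Counting error.** Microscopy counting errors for TEP span roughly
3–20 %; `abundance_with_error()` applies a conservative default of 20 % to
the *total* abundance (`counting_error` is a parameter). Applying it
per class instead would be a different model of the enumeration process;
since the reported ± values in this kind of work accompany totals, the
total-level convention is the default and a per-class treatment is left to
the caller (scale the counts before summarizing).

## 2. The synthetic TEP generator

`simulate_tep_counts()` emulates the enumeration process, not just its
summary statistics:

1. Expected class shares are the *exact* integral of $d_p^{\delta}$ over
   each class, $\left[d_p^{\delta+1}/(\delta+1)\right]$ across the
   boundaries (logarithmic antiderivative at $\delta = -1$), normalized to
   1 — not the mid-point value times the width — so recovery tests isolate
   fitting bias from discretization bias.
2. The particles that are physically counted come from a filtered aliquot:
   `total_abundance * sample_volume_ml` particles (default aliquot 40 mL,
   the volume filtered in the reference protocol) are allocated across
   classes by a single multinomial draw and divided by the aliquot volume
   to return concentrations. This matters: a multinomial over only
   `total_abundance` particles would make the sparse large-size tail far
   noisier than the real measurement, and the zero-truncation of that tail
   visibly biases the fitted slope for steep spectra.
3. Counting error is one whole-sample multiplicative lognormal factor with
   CV = `counting_cv` (mean 1), matching the total-abundance error
   convention of section 1. A common factor shifts $k$ and the abundance
   but leaves $\delta$ untouched, which is also why the slope-recovery
   tests are informative about the multinomial sampling alone.

`simulate_tep_timeseries()` strings samples along the post-seeding sampling
schedule (default 1, 6, 12, 24, 48, 72, 96, 144 h): expected abundance
decays exponentially from `peak_abundance` (default 1.4 × 10⁴ # mL⁻¹, the
order of the observed post-seeding maxima) at `decline_rate` (default
0.0083 h⁻¹, reproducing a decline from ~1.4 × 10⁴ to ~4.4 × 10³ # mL⁻¹
over 144 h), while $\delta$ drifts linearly in log-time from `delta_start`
(−2.0) to `delta_end` (−3.2), the observed flattening-to-steepening range.
Log-time interpolation mirrors the log-scaled time axis on which these
trajectories are roughly linear.

What the generator does **not** emulate: aggregation/coagulation dynamics
(the mid-experiment $\delta$ and $D_{av}$ peaks seen when aggregates form
before settling), magnification-dependent counting corrections, and any
coupling between abundance decline and slope drift. Passing recovery tests
therefore demonstrates that the estimators are unbiased under the assumed
power-law + multinomial + lognormal measurement model — not that real
spectra are power laws.

**Determinism.** All simulators take a `seed`; a fixed seed and parameter
set reproduces the draw bit-for-bit, and the caller's RNG stream is left
untouched (`withr::with_seed` semantics).

## 3. Sediment-trap budgets

Trap chemistry gives, per sample, %TC, %Ca, %Al (all weight % of dry mass)
and the trap Al mass (mg). The budget chain:

* $\%\mathrm{PIC} = \%\mathrm{Ca} \times 12/40$ — all calcium assumed
  carried by calcite; 12 and 40 are the molar masses of C and Ca. A PIC
  exceeding TC violates that assumption and raises an error rather than
  clamping, to surface bad inputs.
* $\%\mathrm{POC} = \%\mathrm{TC} - \%\mathrm{PIC}$; POC stock (mg C)
  $= \%\mathrm{POC} \times$ dry mass $/100$; mmol C $=$ mg$/12$.
* Fluxes divide stocks by the minicosm surface (0.36 m²) and, for daily
  fluxes, the 6-day duration. `poc_flux_total / duration_days ==
  poc_flux_daily` holds identically.
* Aluminium is the lithogenic tracer: dust mass in trap
  $=$ Al mass $/ 0.0412$ (the analog's Al fraction, SD 0.0039);
  "% dust exported" relates it to the 3 600 mg added; the lithogenic flux
  divides it by surface (and duration).

**Dry-mass closure.** Published budget tables of this design print the
composition but not the trap dry mass. When `dry_mass_mg` is absent it is
inferred as `al_mass_mg / al_percent * 100` — the only closure consistent
with the printed tables (e.g. 46.0 mg Al at 5.3 % Al gives 868 mg dry mass,
which at 1.6 % POC returns the printed 13.9 mg stock).

**A deliberate non-reconciliation.** Whenever the trap's %Al exceeds the
analog's 4.12 %, the Al-proxy lithogenic mass exceeds the Al-inferred dry
mass — the two Al measurements are mutually inconsistent (plausibly calcite
dissolution enriching the residue in Al). All six published trap samples
have this property. The budget reports both numbers as-is and emits a
`dustballast_budget_warning`; silently reconciling them would hide a real
feature of the data. Similarly, dust recovery above 100 % warns (the Al
fraction carries ±0.39 % uncertainty) instead of erroring.

`simulate_trap()` inverts this stoichiometry: a chosen fraction of the
added dust reaches the trap, organic matter is mixed in so the
POC-to-dry-mass ratio hits `poc_to_dry_ratio` (default 1.5 %, the observed
ratio; the organic matter is assumed 50 % carbon by mass via
`om_carbon_fraction`, a typical organic-matter carbon content), and %Al,
%Ca and %TC follow from the analog's composition (Ca is 40/100 of calcite
by mass, the same molar-mass convention the PIC step uses — so the round
trip is exact by construction, which is what the zero-noise inversion tests
check). Measurement noise, when requested, is independent multiplicative
lognormal on each measured quantity; no variance model for trap chemistry
is available from the study design, so `measurement_cv` has no anchored
default and tests use 5 %.

## 4. The ballast regression

Across trap budgets, POC flux is modeled as proportional to lithogenic
flux with no intercept — no dust, no ballast-driven export:

$$\hat a = \frac{\sum_i x_i y_i}{\sum_i x_i^2},$$

the closed-form zero-intercept least-squares slope (dimensionless, mg POC
per mg lithogenic material). Daily fluxes (mg m⁻² d⁻¹) are the canonical
axis; because the model is proportional, any common rescaling of both axes
(e.g. 6-day integrated fluxes) leaves the slope and $r^2$ unchanged, so
integrated fluxes are accepted as long as both sides share the basis.

* **$r^2$ convention.** For through-origin fits $r^2$ is ambiguous. The
  package uses the *centered* convention
  $r^2 = 1 - \mathrm{RSS}/\sum (y_i - \bar y)^2$ with residuals from the
  origin fit: it answers "how much of the observed flux variance does the
  proportional model explain", and it is the convention under which the
  fitted six-point regression lands at the published value (the uncentered
  convention $1 - \mathrm{RSS}/\sum y_i^2$ is nearly 1 for any
  positive-sloped cloud and is uninformative here). If all $y$ are
  identical the centered total sum of squares is zero; the fit is then
  reported as $r^2 = 1$ when the residuals are also zero and NaN otherwise.
* **Inference.** The slope's p-value is the standard one-parameter
  regression t-test with $n - 1$ residual degrees of freedom (one
  parameter, no intercept).
* **Extrapolation.** Predictions use the *unrounded* slope. This matters at
  the event scale: the slope prints as 0.012 at three decimals, but
  0.012 × 22 000 mg m⁻² = 264 mg m⁻² rounds to 0.26 g m⁻², whereas the
  unrounded slope (≈ 0.01235) gives 272 mg m⁻² → 0.27 g m⁻², consistent
  with the published estimate. `contribution_fraction()` then expresses a
  POC$_{litho}$ flux as a percentage of a total POC export on the same
  time basis.
* **Validation points.** The two in-situ mesocosm reference points
  (`dune_reference()`) are *not* fit inputs — the regression is attributed
  to the six minicosm points alone — but the fitted line predicts their
  POC$_{litho}$ fluxes to within 25 %, which the test suite checks.

## 5. Reproduction of the published tables

`chipie_budget_inputs()` ships the published per-minicosm trap inputs (POC
%, POC stocks, Al % and Al masses for three seasonal experiments × two pH
treatments) as a packaged CSV; these are printed values, rounded to 0.1 mg
(stocks), 0.1 % (percentages) and 0.1/10 mg m⁻² (fluxes).
`reproduce_study()` recomputes all 24 derived cells and compares them at a
1 % relative tolerance, which is the agreement the printed rounding
supports: recomputing from rounded inputs cannot beat the rounding of the
printed outputs. Two cells (one dust-export percentage, one lithogenic
flux) differ from the printed value by exactly one unit of printed
precision — they were evidently printed from unrounded Al masses — and the
centered $r^2$ of the six-point regression recomputed from printed inputs
is 0.9843 against a printed 0.985, the same one-ulp effect. The
acceptance tests therefore pin the anchor cells to printed precision and
the remainder to one printed ulp / 1 % relative.

## 6. Problem sizes and numerical tolerances in the test suite

* Exact-recovery tests build counts exactly on the power law and require
  $|\hat\delta - \delta| < 10^{-9}$; the slope must also match a
  hand-written normal-equations oracle to $10^{-9}$, and the ballast slope
  a refined grid-search oracle to $10^{-6}$ — dual routes, independent of
  the implementation path.
* Monte-Carlo slope recovery runs 200 replicates per $\delta \in
  \{-1.7, -2.1, -3.3\}$ at total abundance $10^4$ # mL⁻¹ with the default
  40 mL aliquot and 20 % counting CV, requiring mean bias $< 0.05$; the
  shorter in-module variant uses 50 replicates. Trap-recovery uses 500
  replicates at 5 % noise (bias $< 1\%$), and the end-to-end
  pipeline checks the mean fitted slope over replicate three-season
  experiments against the generating POC:litho ratio within 5 %.
* Budget comparisons use 1 % relative tolerance (section 5).

## 7. Known limitations

* The power-law spectrum is an assumption, not a finding of this package;
  real TEP spectra can curve, and the fit reports $r^2$ and `n_bins_used`
  so users can judge adequacy per sample.
* The PIC step attributes all calcium to calcite; gypsum or Ca adsorbed on
  clays would bias %POC low (such inputs surface as composition errors
  only when PIC exceeds TC).
* The Al proxy assumes the dust analog is the sole aluminium source;
  natural systems with lithogenic background would need a blank
  correction, which the package does not model.
* The ballast slope is an empirical proportionality for one region and one
  dust analog; extrapolations inherit that scope, and annual-scale
  application additionally assumes the event-scale proportionality
  averages over the year.
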