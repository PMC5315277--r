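# run `code` under a fixed seed without disturbing the caller's RNG stream
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Expected class proportions under a power-law size spectrum
#'
#' Integrates dN/d(dp) = dp^delta exactly over each size class and
#' normalizes, giving the expected share of particles per class. The
#' antiderivative is `dp^(delta+1)/(delta+1)` except at `delta = -1`, where
#' it is `log(dp)`.
#'
#' @param grid A size-class grid from [build_size_grid()].
#' @param delta Spectral slope (typically negative).
#'
#' @return A numeric vector of per-class probabilities summing to 1.
#'
#' @export
size_class_probabilities <- function(grid, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta)) {
    abort("`delta` must be a single finite number.",
          class = "dustballast_sim_error")
  }
  lo <- grid$lower_um
  hi <- grid$upper_um
  mass <- if (abs(delta + 1) < 1e-12) {
    log(hi) - log(lo)
  } else {
    (hi^(delta + 1) - lo^(delta + 1)) / (delta + 1)
  }
  mass / sum(mass)
}

#' Simulate a TEP count sample from a power-law size spectrum
#'
#' Draws a per-size-class TEP count table whose expectation follows
#' dN/d(dp) proportional to dp^delta. The counting process is emulated
#' physically: the number of particles actually enumerated under the
#' microscope comes from a filtered aliquot of `sample_volume_ml`
#' (40 mL in the reference protocol), so `total_abundance * sample_volume_ml`
#' particles are allocated multinomially across classes with probabilities
#' proportional to the exact power-law integral over each class; counts are
#' then converted back to concentrations (# mL^-1) and a single
#' whole-sample multiplicative lognormal factor with coefficient of
#' variation `counting_cv` represents the enumeration error, which applies
#' to the total abundance (a common factor shifts `k` but leaves the
#' spectral slope untouched).
#'
#' @param grid A size-class grid from [build_size_grid()].
#' @param delta Generating spectral slope (negative for realistic spectra).
#' @param total_abundance Expected total abundance, # mL^-1.
#' @param counting_cv Coefficient of variation of the counting error
#'   (default 0.20, the conservative upper end of the 3-20% range).
#' @param sample_volume_ml Volume of the counted aliquot, mL (default 40).
#' @param seed Optional integer seed; the draw is bit-reproducible for a
#'   fixed seed and parameter set, and the caller's RNG state is restored.
#' @param sample_id Identifier stored in the output.
#'
#' @return A tibble with columns `sample_id`, `class_index`, `count_per_ml`.
#'
#' @examples
#' grid <- build_size_grid()
#' counts <- simulate_tep_counts(grid, delta = -2.1, total_abundance = 1e4,
#'                               seed = 42)
#' fit_spectral_slope(counts, grid)
#'
#' @export
simulate_tep_counts <- function(grid, delta, total_abundance,
                                counting_cv = 0.2, sample_volume_ml = 40,
                                seed = NULL, sample_id = "sim") {
  if (!is.numeric(total_abundance) || total_abundance < 0) {
    abort("`total_abundance` must be non-negative.",
          class = "dustballast_sim_error")
  }
  if (!is.numeric(counting_cv) || counting_cv < 0) {
    abort("`counting_cv` must be non-negative.",
          class = "dustballast_sim_error")
  }
  p <- size_class_probabilities(grid, delta)
  n_counted <- round(total_abundance * sample_volume_ml)
  counts <- with_optional_seed(seed, {
    x <- if (n_counted > 0) {
      as.vector(rmultinom(1, size = n_counted, prob = p)) / sample_volume_ml
    } else {
      rep(0, nrow(grid))
    }
    if (counting_cv > 0) {
      sdlog <- sqrt(log(1 + counting_cv^2))
      x <- x * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    x
  })
  tibble::tibble(sample_id = sample_id, class_index = grid$class_index,
                 count_per_ml = counts)
}

#' Simulate a TEP time series after a dust-seeding event
#'
#' Emulates the post-seeding trajectory observed in dust-seeded minicosms:
#' total TEP abundance is maximal at the first sample after seeding and
#' decays exponentially at `decline_rate`, while the spectral slope drifts
#' linearly in log-time from `delta_start` (flat spectrum, relatively many
#' large freshly formed TEP) to `delta_end` (steep spectrum, small particles
#' dominate as large aggregates settle out). Per-sample counts are drawn
#' with [simulate_tep_counts()].
#'
#' Defaults anchor to the reference experiments: sampling at 1-144 h after
#' seeding, a peak near 1.4e4 # mL^-1, a decline rate reproducing a drop to
#' ~4.4e3 # mL^-1 at 144 h, and a slope drift from -2.0 to -3.2.
#'
#' @param grid A size-class grid from [build_size_grid()].
#' @param sampling_hours Increasing sampling times, hours after seeding.
#' @param peak_abundance Expected abundance at the first sample, # mL^-1.
#' @param decline_rate Exponential decline rate of abundance, h^-1.
#' @param delta_start,delta_end Spectral slope at the first and last sample.
#' @inheritParams simulate_tep_counts
#'
#' @return A tibble with columns `sample_id` (e.g. `"T24"`), `hours`,
#'   `class_index`, `count_per_ml`.
#'
#' @export
simulate_tep_timeseries <- function(grid,
                                    sampling_hours = c(1, 6, 12, 24, 48, 72,
                                                       96, 144),
                                    peak_abundance = 14000,
                                    decline_rate = 0.0083,
                                    delta_start = -2.0, delta_end = -3.2,
                                    counting_cv = 0.2, sample_volume_ml = 40,
                                    seed = NULL) {
  if (is.unsorted(sampling_hours, strictly = TRUE) ||
      any(sampling_hours <= 0)) {
    abort("`sampling_hours` must be positive and strictly increasing.",
          class = "dustballast_sim_error")
  }
  t0 <- sampling_hours[1]
  tn <- sampling_hours[length(sampling_hours)]
  frac <- if (tn > t0) {
    (log(sampling_hours) - log(t0)) / (log(tn) - log(t0))
  } else {
    rep(0, length(sampling_hours))
  }
  abundance <- peak_abundance * exp(-decline_rate * (sampling_hours - t0))
  delta <- delta_start + (delta_end - delta_start) * frac
  with_optional_seed(seed, {
    purrr::pmap(
      list(sampling_hours, abundance, delta),
      function(h, a, d) {
        simulate_tep_counts(grid, delta = d, total_abundance = a,
                            counting_cv = counting_cv,
                            sample_volume_ml = sample_volume_ml,
                            sample_id = sprintf("T%g", h)) |>
          dplyr::mutate(hours = h, .after = "sample_id")
      }
    ) |>
      purrr::list_rbind()
  })
}

#' Simulate a sediment-trap composition
#'
#' Builds a trap sample by mixing the dust analog with organic matter,
#' inverting the stoichiometry that [trap_budget()] later applies: a fraction
#' `dust_fraction_exported` of the added dust reaches the trap; organic
#' matter is added so that the POC-to-dry-weight ratio equals
#' `poc_to_dry_ratio`; aluminium and calcium contents follow from the
#' analog's Al and calcite fractions (Ca is 40/100 of calcite by mass, the
#' same molar-mass convention the PIC calculation uses); and %TC is the sum
#' of the PIC and POC contributions. Optional multiplicative lognormal noise
#' at `measurement_cv` perturbs each measured quantity (%TC, %Ca, %Al and
#' the Al mass) independently.
#'
#' @param dust_fraction_exported Fraction of the added dust reaching the
#'   trap, in `[0, 1]`.
#' @param poc_to_dry_ratio POC as a percentage of trap dry weight
#'   (default 1.5, the ratio observed across the reference experiments).
#' @param measurement_cv Coefficient of variation of the measurement noise
#'   (0 = exact).
#' @param dust A [dust_analog()] specification.
#' @param config A [minicosm()] configuration (carried for downstream flux
#'   computations; the composition itself does not use it).
#' @param om_carbon_fraction Carbon content of the organic matter by mass,
#'   used to convert POC carbon into organic dry mass (default 0.5).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param label Identifier stored in the output.
#'
#' @return A one-row tibble with columns `label`, `tc_percent`,
#'   `ca_percent`, `al_percent`, `al_mass_mg`, ready for [trap_budget()].
#'   The generating truth (dust, organic and dry masses, POC stock) is
#'   attached as attribute `"truth"`.
#'
#' @examples
#' trap <- simulate_trap(dust_fraction_exported = 0.31,
#'                       poc_to_dry_ratio = 1.6)
#' trap_budget(trap)  # recovers 31% exported and 1.6% POC exactly
#'
#' @export
simulate_trap <- function(dust_fraction_exported, poc_to_dry_ratio = 1.5,
                          measurement_cv = 0, dust = dust_analog(),
                          config = minicosm(), om_carbon_fraction = 0.5,
                          seed = NULL, label = "sim") {
  if (!is.numeric(dust_fraction_exported) || dust_fraction_exported < 0 ||
      dust_fraction_exported > 1) {
    abort("`dust_fraction_exported` must lie in [0, 1].",
          class = "dustballast_sim_error")
  }
  if (poc_to_dry_ratio < 0 || om_carbon_fraction <= 0 ||
      om_carbon_fraction > 1) {
    abort("invalid `poc_to_dry_ratio` or `om_carbon_fraction`.",
          class = "dustballast_sim_error")
  }
  om_share <- poc_to_dry_ratio / (100 * om_carbon_fraction)
  if (om_share >= 1) {
    abort("`poc_to_dry_ratio` is infeasible for this `om_carbon_fraction`.",
          class = "dustballast_sim_error")
  }
  dust_mass <- dust_fraction_exported * dust$mass_added_mg
  dry_mass <- dust_mass / (1 - om_share)
  om_mass <- dry_mass - dust_mass
  poc_mass <- om_mass * om_carbon_fraction

  al_mass <- dust$al_fraction * dust_mass
  al_pct <- if (dry_mass > 0) al_mass / dry_mass * 100 else 0
  ca_pct <- if (dry_mass > 0) {
    dust$calcite_fraction * dust_mass * (40 / 100) / dry_mass * 100
  } else 0
  pic_pct <- ca_pct * 12 / 40
  poc_pct <- if (dry_mass > 0) poc_mass / dry_mass * 100 else 0
  tc_pct <- pic_pct + poc_pct

  measured <- c(tc = tc_pct, ca = ca_pct, al = al_pct, al_mass = al_mass)
  if (measurement_cv > 0) {
    measured <- with_optional_seed(seed, {
      sdlog <- sqrt(log(1 + measurement_cv^2))
      measured * rlnorm(4, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  }

  out <- tibble::tibble(
    label = label,
    tc_percent = unname(measured["tc"]),
    ca_percent = unname(measured["ca"]),
    al_percent = unname(measured["al"]),
    al_mass_mg = unname(measured["al_mass"])
  )
  attr(out, "truth") <- list(
    dust_mass_mg = dust_mass, om_mass_mg = om_mass, dry_mass_mg = dry_mass,
    poc_mass_mg = poc_mass, dust_fraction_exported = dust_fraction_exported,
    poc_to_dry_ratio = poc_to_dry_ratio
  )
  out
}
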