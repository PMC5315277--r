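#' Published CHIPIE sediment-trap measurements
#'
#' The per-minicosm sediment-trap values published for the three CHIPIE
#' dust-seeding experiments (each with a non-acidified "NA" and an acidified
#' "A" minicosm): POC weight percentage, POC stock (mmol and mg of carbon),
#' aluminium content (% of dry weight) and aluminium mass (mg). These are
#' the inputs from which every derived budget quantity (fluxes, dust
#' recovery, lithogenic fluxes, the ballast regression) can be recomputed.
#'
#' @return A tibble with one row per experiment x treatment and columns
#'   `experiment`, `treatment`, `label`, `poc_percent`, `poc_stock_mmol`,
#'   `poc_stock_mg`, `al_percent`, `al_mass_mg`.
#'
#' @examples
#' chipie_budget_inputs()
#'
#' @export
chipie_budget_inputs <- function() {
  path <- system.file("extdata", "chipie_traps.csv", package = "dustballast",
                      mustWork = TRUE)
  readr::read_csv(path, na = "", show_col_types = FALSE) |>
    dplyr::mutate(label = paste(.data$experiment, .data$treatment),
                  .after = "treatment")
}

#' Published derived budget values for comparison
#'
#' The derived sediment-trap quantities as published for the CHIPIE
#' experiments (POC flux over six days and per day, percentage of dust
#' exported, lithogenic flux over six days), used to verify the package's
#' recomputation against the printed values.
#'
#' @return A tibble with one row per experiment x treatment.
#'
#' @export
chipie_printed <- function() {
  path <- system.file("extdata", "chipie_printed.csv",
                      package = "dustballast", mustWork = TRUE)
  readr::read_csv(path, na = "", show_col_types = FALSE) |>
    dplyr::mutate(label = paste(.data$experiment, .data$treatment),
                  .after = "treatment")
}

#' DUNE in-situ mesocosm reference fluxes
#'
#' Six-day integrated lithogenic and primary-production-normalized POC_litho
#' fluxes from the two DUNE in-situ dust-seeding mesocosm experiments in the
#' same Mediterranean region. They are validation points for the ballast
#' regression, not fit inputs: the fitted line should predict them to
#' within roughly a quarter.
#'
#' @return A tibble with columns `label`, `litho_flux_total` (mg m^-2 per
#'   6 d) and `poc_litho_flux_total` (mg m^-2 per 6 d).
#'
#' @export
dune_reference <- function() {
  tibble::tibble(
    label = c("DUNE R1", "DUNE R2"),
    litho_flux_total = c(3342, 2139),
    poc_litho_flux_total = c(31, 23)
  )
}

#' Daily flux pairs for the ballast regression
#'
#' Derives the six (lithogenic flux, POC flux) daily pairs that the ballast
#' regression is fitted on: the POC side from each trap's published POC
#' stock and the minicosm geometry, the lithogenic side from each trap's
#' aluminium mass via the Al-proxy.
#'
#' @param dust A [dust_analog()] specification.
#' @param config A [minicosm()] configuration.
#'
#' @return A tibble with columns `label`, `litho_flux_daily`,
#'   `poc_flux_daily` (mg m^-2 d^-1).
#'
#' @examples
#' fit_ballast(chipie_flux_points())
#'
#' @export
chipie_flux_points <- function(dust = dust_analog(), config = minicosm()) {
  inputs <- chipie_budget_inputs()
  tibble::tibble(
    label = inputs$label,
    litho_flux_daily = lithogenic_flux(inputs$al_mass_mg, dust,
                                       config)$litho_flux_daily,
    poc_flux_daily = poc_flux(inputs$poc_stock_mg, config)$poc_flux_daily
  )
}

#' Recompute every derived CHIPIE quantity and compare with the published values
#'
#' Re-runs the full quantitative chain from the published trap inputs:
#' POC fluxes from the POC stocks, dust recovery and lithogenic fluxes from
#' the aluminium masses, the zero-intercept ballast regression over the six
#' daily flux pairs, and the event-scale and annual-scale extrapolations.
#' Each recomputed cell is compared with its published counterpart at a
#' relative tolerance (default 1%, reflecting the rounding of the published
#' tables).
#'
#' @param dust A [dust_analog()] specification.
#' @param config A [minicosm()] configuration.
#' @param tolerance Relative tolerance for cell comparisons.
#'
#' @return An object of class `chipie_reproduction`: a list with
#'   `comparison` (tibble of recomputed vs published cells with relative
#'   errors), `fit` (the `ballast_fit`), `extrapolations` (tibble), and
#'   `all_within_tolerance` (logical).
#'
#' @examples
#' rep <- reproduce_study()
#' rep$extrapolations
#'
#' @export
reproduce_study <- function(dust = dust_analog(), config = minicosm(),
                            tolerance = 0.01) {
  inputs <- chipie_budget_inputs()
  printed <- chipie_printed()

  pf <- poc_flux(inputs$poc_stock_mg, config)
  rec <- dust_recovery(inputs$al_mass_mg, dust)
  lf <- lithogenic_flux(inputs$al_mass_mg, dust, config)

  computed <- tibble::tibble(
    label = inputs$label,
    poc_flux_total = pf$poc_flux_total,
    poc_flux_daily = pf$poc_flux_daily,
    dust_exported_percent = rec$dust_exported_percent,
    litho_flux_total = lf$litho_flux_total
  )
  comparison <- computed |>
    tidyr::pivot_longer(-"label", names_to = "quantity",
                        values_to = "computed") |>
    dplyr::left_join(
      printed |>
        dplyr::select("label", "poc_flux_total", "poc_flux_daily",
                      "dust_exported_percent", "litho_flux_total") |>
        tidyr::pivot_longer(-"label", names_to = "quantity",
                            values_to = "printed"),
      by = c("label", "quantity")
    ) |>
    dplyr::mutate(
      rel_err = abs(.data$computed - .data$printed) / abs(.data$printed),
      within_tol = .data$rel_err <= tolerance
    )

  fit <- fit_ballast(chipie_flux_points(dust, config))

  event_litho_g <- 22    # extreme Saharan event, g m^-2
  event_total_poc_g <- 0.8
  annual_dust_g <- 11.4
  annual_poc_g <- 2.4
  event_poc_g <- predict_poc_litho(fit, event_litho_g * 1000) / 1000
  annual_poc_litho_g <- predict_poc_litho(fit, annual_dust_g * 1000) / 1000
  extrapolations <- tibble::tibble(
    scale = c("event", "annual"),
    litho_input_g_m2 = c(event_litho_g, annual_dust_g),
    poc_litho_g_m2 = c(event_poc_g, annual_poc_litho_g),
    total_poc_g_m2 = c(event_total_poc_g, annual_poc_g),
    contribution_percent = contribution_fraction(
      c(event_poc_g, annual_poc_litho_g),
      c(event_total_poc_g, annual_poc_g)
    )
  )

  structure(
    list(comparison = comparison, fit = fit, extrapolations = extrapolations,
         all_within_tolerance = all(comparison$within_tol)),
    class = "chipie_reproduction"
  )
}

#' @export
print.chipie_reproduction <- function(x, ...) {
  cat("CHIPIE reproduction report\n")
  cat(sprintf("  budget cells within tolerance: %d / %d\n",
              sum(x$comparison$within_tol), nrow(x$comparison)))
  cat(sprintf("  max relative error: %.3g\n", max(x$comparison$rel_err)))
  cat(sprintf("  ballast slope %.5f, r^2 %.4f, p %.2g\n",
              x$fit$slope, x$fit$r_squared, x$fit$p_value))
  cat(sprintf("  event-scale POC_litho %.2f g m^-2 (%.0f%% of export); ",
              x$extrapolations$poc_litho_g_m2[1],
              x$extrapolations$contribution_percent[1]))
  cat(sprintf("annual contribution ~%.0f%%\n",
              x$extrapolations$contribution_percent[2]))
  invisible(x)
}

#' Run the full analysis pipeline on count and trap tables
#'
#' Orchestrates the three analysis stages over tabular inputs: TEP
#' size-spectrum summaries from a count table, sediment-trap budgets from a
#' composition table, and the ballast regression over the budget's daily
#' fluxes. Inputs may be data frames or CSV paths; outputs are written to
#' `out_dir` as `tep_summary.csv`, `trap_budget.csv` and `ballast_fit.json`,
#' together with a `run_info.json` recording every parameter, the seed and
#' MD5 checksums of any file inputs.
#'
#' @param counts A TEP count table (`sample_id`, `class_index`,
#'   `count_per_ml`) or a CSV path, or `NULL` to skip the spectrum stage.
#' @param traps A trap composition table (see [trap_budget()]) or a CSV
#'   path, or `NULL` to skip the budget and ballast stages.
#' @param out_dir Output directory (created if absent).
#' @param grid A size-class grid from [build_size_grid()].
#' @param dust A [dust_analog()] specification.
#' @param config A [minicosm()] configuration.
#' @param counting_error Fractional counting error for abundance SDs.
#' @param seed Optional integer seed recorded in `run_info.json` and applied
#'   before any stage (the pipeline itself is deterministic; the seed matters
#'   when `counts`/`traps` come from the simulators upstream).
#'
#' @return Invisibly, a list with elements `tep_summary`, `budget`, `fit`
#'   and `paths`.
#'
#' @export
run_pipeline <- function(counts = NULL, traps = NULL, out_dir,
                         grid = build_size_grid(), dust = dust_analog(),
                         config = minicosm(), counting_error = 0.2,
                         seed = NULL) {
  if (is.null(counts) && is.null(traps)) {
    abort("nothing to do: supply `counts` and/or `traps`.",
          class = "dustballast_config_error")
  }
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  checksums <- list()
  read_input <- function(x, what) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        abort(sprintf("%s file not found: %s", what, x),
              class = "dustballast_config_error")
      }
      checksums[[what]] <<- unname(tools::md5sum(x))
      df <- readr::read_csv(x, na = "", show_col_types = FALSE)
      if (nrow(df) == 0) {
        abort(sprintf("%s file has no rows: %s", what, x),
              class = "dustballast_parse_error")
      }
      df
    } else {
      tibble::as_tibble(x)
    }
  }

  results <- list(paths = character())
  if (!is.null(counts)) {
    counts <- read_input(counts, "counts")
    results$tep_summary <- tep_summary(counts, grid, counting_error)
    p <- file.path(out_dir, "tep_summary.csv")
    readr::write_csv(results$tep_summary, p)
    results$paths <- c(results$paths, tep_summary = p)
  }
  if (!is.null(traps)) {
    traps <- read_input(traps, "traps")
    results$budget <- trap_budget(traps, dust, config)
    p <- file.path(out_dir, "trap_budget.csv")
    readr::write_csv(results$budget, p)
    results$paths <- c(results$paths, budget = p)
    if (nrow(results$budget) >= 2 &&
        any(results$budget$litho_flux_daily > 0)) {
      results$fit <- fit_ballast(results$budget)
      pj <- file.path(out_dir, "ballast_fit.json")
      jsonlite::write_json(
        list(slope = results$fit$slope, r_squared = results$fit$r_squared,
             p_value = results$fit$p_value, n_points = results$fit$n_points,
             residuals = setNames(as.list(results$fit$data$residual),
                                  results$fit$data$label)),
        pj, auto_unbox = TRUE, digits = NA
      )
      results$paths <- c(results$paths, ballast = pj)
    }
  }

  params <- list(
    grid = list(d_min = min(grid$lower_um), d_max = max(grid$upper_um),
                n_classes = nrow(grid)),
    dust = unclass(dust), minicosm = unclass(config),
    counting_error = counting_error, seed = seed
  )
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(params, cfg_file, auto_unbox = TRUE, digits = NA)
  info <- list(parameters = params,
               config_hash = unname(tools::md5sum(cfg_file)),
               input_checksums = checksums)
  unlink(cfg_file)
  pi_path <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(info, pi_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  results$paths <- c(results$paths, run_info = pi_path)
  invisible(results)
}
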