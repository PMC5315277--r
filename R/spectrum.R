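#' Width-normalized number size distribution
#'
#' Standardizes per-class TEP counts by the width of their size class, giving
#' the discrete number size distribution dN/d(dp) in # mL^-1 um^-1. This is
#' the quantity whose log-log relationship with the class mid-point diameter
#' defines the spectral slope.
#'
#' @param counts A data frame of per-class counts with columns `sample_id`,
#'   `class_index` and `count_per_ml` (one row per sample x class; extra
#'   metadata columns are carried through).
#' @param grid A size-class grid from [build_size_grid()].
#'
#' @return `counts` joined with the grid geometry, with an added `dn_ddp`
#'   column (# mL^-1 um^-1).
#'
#' @examples
#' grid <- build_size_grid()
#' counts <- simulate_tep_counts(grid, delta = -2.5, total_abundance = 1e4,
#'                               seed = 1)
#' normalized_distribution(counts, grid)
#'
#' @export
normalized_distribution <- function(counts, grid) {
  check_counts(counts, grid)
  counts |>
    dplyr::left_join(grid, by = "class_index") |>
    dplyr::mutate(dn_ddp = .data$count_per_ml / .data$width_um)
}

#' Fit the power-law spectral slope of a TEP size distribution
#'
#' Fits the number size distribution dN/d(dp) = k * dp^delta by ordinary
#' least squares of log10(dN/d(dp)) on log10(dp) over the classes with
#' strictly positive counts. The spectral slope delta summarizes the relative
#' abundance of small versus large particles (more negative = relatively more
#' small particles); `k` scales with particle concentration. Zero-count
#' classes are excluded (their logarithm is undefined) and no pseudo-count is
#' added; `n_bins_used` records how many classes entered each fit.
#'
#' @inheritParams normalized_distribution
#'
#' @return A tibble with one row per sample: `sample_id`, `delta`, `k`,
#'   `r_squared`, `n_bins_used`.
#'
#' @examples
#' grid <- build_size_grid()
#' # counts built exactly from dN/d(dp) = 1000 * dp^-2 are recovered exactly
#' counts <- tibble::tibble(
#'   sample_id = "exact", class_index = grid$class_index,
#'   count_per_ml = 1000 * grid$midpoint_um^-2 * grid$width_um
#' )
#' fit_spectral_slope(counts, grid)
#'
#' @export
fit_spectral_slope <- function(counts, grid) {
  nd <- normalized_distribution(counts, grid)
  nd |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      fit_slope_one(df$midpoint_um, df$dn_ddp, sample_id = key$sample_id)
    }) |>
    dplyr::ungroup()
}

fit_slope_one <- function(dp, dn_ddp, sample_id = NULL) {
  pos <- dn_ddp > 0
  if (sum(pos) < 2) {
    abort(
      paste0("spectral slope fit needs at least 2 positive-count classes",
             if (!is.null(sample_id)) paste0(" (sample '", sample_id, "')")),
      class = "dustballast_fit_error"
    )
  }
  ly <- log10(dn_ddp[pos])
  m <- lm(ly ~ log10(dp[pos]))
  cf <- coef(m)
  # computed directly rather than via summary.lm(), which warns on the
  # (legitimate) noise-free perfect-fit case
  tss <- sum((ly - mean(ly))^2)
  rss <- sum(stats::residuals(m)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  tibble::tibble(
    delta = unname(cf[2]),
    k = 10^unname(cf[1]),
    r_squared = r2,
    n_bins_used = sum(pos)
  )
}

#' Abundance-weighted average TEP diameter
#'
#' Computes the mean particle diameter D_av (um), weighting each class
#' mid-point diameter by its TEP abundance:
#' D_av = sum_i N(dp_i) dp_i / sum_i N(dp_i).
#'
#' @inheritParams normalized_distribution
#'
#' @return A tibble with one row per sample: `sample_id`, `d_av_um`. The
#'   value always lies between the smallest and largest class mid-point.
#'
#' @export
average_diameter <- function(counts, grid) {
  nd <- normalized_distribution(counts, grid)
  nd |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      total = sum(.data$count_per_ml),
      d_av_um = if (sum(.data$count_per_ml) > 0) {
        weighted.mean(.data$midpoint_um, .data$count_per_ml)
      } else NA_real_,
      .groups = "drop"
    ) |>
    (\(x) {
      if (any(x$total == 0)) {
        abort("average diameter is undefined for all-zero counts.",
              class = "dustballast_fit_error")
      }
      dplyr::select(x, "sample_id", "d_av_um")
    })()
}

#' TEP volume concentration
#'
#' Computes the total TEP volume per water volume, C_v (ppm, v/v), assuming
#' spherical particles at the class mid-point diameter:
#' C_v = sum_i (pi/6) dp_i^3 N(dp_i) 1e-6, with dp_i in um and N in # mL^-1
#' (1 um^3 mL^-1 = 1e-12 v/v, so the 1e-6 factor yields parts per million).
#'
#' @inheritParams normalized_distribution
#'
#' @return A tibble with one row per sample: `sample_id`, `cv_ppm`.
#'
#' @export
volume_concentration <- function(counts, grid) {
  nd <- normalized_distribution(counts, grid)
  nd |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      cv_ppm = sum(pi / 6 * .data$midpoint_um^3 * .data$count_per_ml) * 1e-6,
      .groups = "drop"
    )
}

#' Total TEP abundance with counting uncertainty
#'
#' Sums per-class counts into the total TEP abundance (# mL^-1) and attaches
#' a standard deviation computed as a fixed fraction of the total. Microscopy
#' counting errors for TEP range from about 3 to 20%; the default takes the
#' conservative upper end, 20%, applied to the total abundance.
#'
#' @param counts A data frame with columns `sample_id` and `count_per_ml`.
#' @param counting_error Fractional counting error applied to the total
#'   abundance (default 0.20).
#'
#' @return A tibble with one row per sample: `sample_id`, `abundance`
#'   (# mL^-1), `abundance_sd` (# mL^-1).
#'
#' @examples
#' counts <- tibble::tibble(sample_id = "a", class_index = 1:3,
#'                          count_per_ml = c(14000, 400, 49))
#' abundance_with_error(counts)  # 14449 +/- 2890
#'
#' @export
abundance_with_error <- function(counts, counting_error = 0.2) {
  if (!is.numeric(counting_error) || counting_error < 0) {
    abort("`counting_error` must be a non-negative fraction.",
          class = "dustballast_shape_error")
  }
  if (!all(c("sample_id", "count_per_ml") %in% names(counts))) {
    abort("`counts` needs columns `sample_id` and `count_per_ml`.",
          class = "dustballast_shape_error")
  }
  counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(abundance = sum(.data$count_per_ml), .groups = "drop") |>
    dplyr::mutate(abundance_sd = counting_error * .data$abundance)
}

#' Per-sample summary of TEP size-spectrum statistics
#'
#' One-stop summary combining total abundance (with counting uncertainty),
#' the fitted power-law spectral slope, the abundance-weighted mean diameter
#' and the volume concentration for every sample in a count table.
#'
#' @inheritParams normalized_distribution
#' @inheritParams abundance_with_error
#'
#' @return A tibble with one row per sample and columns `sample_id`,
#'   `abundance`, `abundance_sd`, `delta`, `k`, `r_squared`, `n_bins_used`,
#'   `d_av_um`, `cv_ppm`.
#'
#' @examples
#' grid <- build_size_grid()
#' counts <- simulate_tep_timeseries(grid, seed = 7)
#' tep_summary(counts, grid)
#'
#' @export
tep_summary <- function(counts, grid, counting_error = 0.2) {
  abundance_with_error(counts, counting_error) |>
    dplyr::left_join(fit_spectral_slope(counts, grid), by = "sample_id") |>
    dplyr::left_join(average_diameter(counts, grid), by = "sample_id") |>
    dplyr::left_join(volume_concentration(counts, grid), by = "sample_id")
}

#' Plot a TEP number size distribution with its power-law fit
#'
#' Log-log scatter of the width-normalized size distribution against class
#' mid-point diameter, one panel-free layer per sample, overlaid with each
#' sample's fitted power law dN/d(dp) = k * dp^delta.
#'
#' @inheritParams normalized_distribution
#'
#' @return A ggplot object.
#'
#' @export
plot_size_spectrum <- function(counts, grid) {
  nd <- normalized_distribution(counts, grid) |>
    dplyr::filter(.data$dn_ddp > 0)
  fits <- fit_spectral_slope(counts, grid) |>
    dplyr::mutate(label = sprintf("%s (delta = %.1f)", .data$sample_id,
                                  .data$delta))
  lines <- fits |>
    dplyr::cross_join(tibble::tibble(midpoint_um = exp(seq(log(min(grid$midpoint_um)),
                                                           log(max(grid$midpoint_um)),
                                                           length.out = 50)))) |>
    dplyr::mutate(dn_ddp = .data$k * .data$midpoint_um^.data$delta)
  ggplot2::ggplot(nd, ggplot2::aes(.data$midpoint_um, .data$dn_ddp,
                                   colour = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mid-point diameter (µm)",
                  y = expression(dN / d(d[p]) ~ ("#" ~ mL^-1 ~ mu * m^-1)),
                  colour = "sample") +
    ggplot2::theme_minimal()
}
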