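test_that("logarithmic size grid has geometric boundaries and exact endpoints", {
  grid <- build_size_grid(1, 135, 15)
  expect_equal(nrow(grid), 15)
  expect_equal(grid$lower_um[1], 1)
  expect_equal(grid$upper_um[15], 135)

  ratio <- grid$upper_um / grid$lower_um
  expect_equal(ratio, rep(135^(1 / 15), 15))
  expect_equal(135^(1 / 15), 1.3867, tolerance = 1e-4)
  expect_equal(grid$width_um[1], 135^(1 / 15) - 1)
  expect_equal(grid$width_um[1], 0.3867, tolerance = 1e-3)

  # self-consistency: widths tile the range, boundary ratios compound
  expect_equal(sum(grid$width_um), 135 - 1)
  expect_equal(prod(ratio), 135)

  # midpoints strictly inside their class, widths positive
  expect_true(all(grid$midpoint_um > grid$lower_um &
                    grid$midpoint_um < grid$upper_um))
  expect_true(all(grid$width_um > 0))

  geo <- build_size_grid(1, 135, 15, midpoint = "geometric")
  expect_equal(geo$midpoint_um, sqrt(geo$lower_um * geo$upper_um))
  expect_true(all(geo$midpoint_um < grid$midpoint_um))  # AM-GM
})

test_that("single-class grid and invalid ranges behave as specified", {
  g <- build_size_grid(2, 4, 1)
  expect_equal(g$midpoint_um, 3)
  expect_equal(g$width_um, 2)

  expect_error(build_size_grid(0, 135, 15), class = "dustballast_grid_error")
  expect_error(build_size_grid(10, 2, 5), class = "dustballast_grid_error")
  expect_error(build_size_grid(1, 135, 0), class = "dustballast_grid_error")
  expect_error(build_size_grid(1, 135, 2.5), class = "dustballast_grid_error")
})

test_that("width normalization divides counts by class width", {
  grid <- build_size_grid(1, 135, 15)
  counts <- tibble::tibble(sample_id = "s", class_index = 1:15,
                           count_per_ml = c(100, rep(0, 14)))
  nd <- normalized_distribution(counts, grid)
  expect_equal(nd$dn_ddp[1], 100 / (135^(1 / 15) - 1))
  expect_equal(nd$dn_ddp[1], 258.6, tolerance = 1e-3)
  expect_equal(nd$dn_ddp[-1], rep(0, 14))

  # linearity
  nd2 <- normalized_distribution(
    dplyr::mutate(counts, count_per_ml = 2 * count_per_ml), grid)
  expect_equal(nd2$dn_ddp, 2 * nd$dn_ddp)

  # shape errors
  expect_error(normalized_distribution(counts[1:7, ], grid),
               class = "dustballast_shape_error")
  expect_error(
    normalized_distribution(
      dplyr::mutate(counts, count_per_ml = replace(count_per_ml, 2, -1)),
      grid),
    class = "dustballast_shape_error")
})

test_that("spectral slope fit recovers an exact power law to 1e-9", {
  grid <- build_size_grid(1, 135, 15)
  counts <- exact_power_law_counts(grid, k = 1000, delta = -2)
  fit <- fit_spectral_slope(counts, grid)
  expect_equal(fit$delta, -2, tolerance = 1e-9)
  expect_equal(fit$k, 1000, tolerance = 1e-6)
  expect_equal(fit$n_bins_used, 15)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("slope fit matches an independent normal-equations oracle", {
  grid <- build_size_grid(1, 135, 15)
  withr::local_seed(101)
  for (i in 1:20) {
    counts <- tibble::tibble(
      sample_id = "s", class_index = 1:15,
      count_per_ml = stats::rlnorm(15, meanlog = 3, sdlog = 1)
    )
    fit <- fit_spectral_slope(counts, grid)
    nd <- normalized_distribution(counts, grid)
    oracle <- ols_slope_oracle(nd$midpoint_um, nd$dn_ddp)
    expect_equal(fit$delta, unname(oracle["slope"]), tolerance = 1e-9)
    expect_equal(log10(fit$k), unname(oracle["intercept"]),
                 tolerance = 1e-9)
  }
})

test_that("zero-count classes are dropped and sparse samples error", {
  grid <- build_size_grid(1, 135, 15)
  counts <- exact_power_law_counts(grid, delta = -2.5)
  counts$count_per_ml[c(3, 9, 14)] <- 0
  fit <- fit_spectral_slope(counts, grid)
  expect_equal(fit$n_bins_used, 12)
  expect_equal(fit$delta, -2.5, tolerance = 1e-9)  # remaining points exact

  one_pos <- dplyr::mutate(counts,
                           count_per_ml = replace(rep(0, 15), 5, 10))
  expect_error(fit_spectral_slope(one_pos, grid),
               class = "dustballast_fit_error")
})

test_that("scaling counts leaves delta and D_av unchanged, scales abundance and C_v", {
  grid <- build_size_grid(1, 135, 15)
  withr::local_seed(7)
  counts <- simulate_tep_counts(grid, delta = -2.4, total_abundance = 5e3)
  scaled <- dplyr::mutate(counts, count_per_ml = 3.7 * count_per_ml)

  expect_equal(fit_spectral_slope(scaled, grid)$delta,
               fit_spectral_slope(counts, grid)$delta, tolerance = 1e-12)
  expect_equal(average_diameter(scaled, grid)$d_av_um,
               average_diameter(counts, grid)$d_av_um, tolerance = 1e-12)
  expect_equal(abundance_with_error(scaled)$abundance,
               3.7 * abundance_with_error(counts)$abundance)
  expect_equal(volume_concentration(scaled, grid)$cv_ppm,
               3.7 * volume_concentration(counts, grid)$cv_ppm)
})

test_that("average diameter is the abundance-weighted mean of midpoints", {
  g1 <- build_size_grid(5, 20, 1)   # single class, midpoint 12.5
  counts <- tibble::tibble(sample_id = "s", class_index = 1,
                           count_per_ml = 500)
  expect_equal(average_diameter(counts, g1)$d_av_um, 12.5)

  # two classes, equal counts -> arithmetic mean of the midpoints
  g2 <- build_size_grid(1, 4, 2)
  eq <- tibble::tibble(sample_id = "s", class_index = 1:2,
                       count_per_ml = c(10, 10))
  expect_equal(average_diameter(eq, g2)$d_av_um, mean(g2$midpoint_um))

  # hand-computed weighted mean on midpoints 1.19 and 4 um:
  # (300*1.19 + 100*4) / 400
  grid <- build_size_grid(1, 135, 15)
  d <- c(1.19, 4)
  counts2 <- tibble::tibble(sample_id = "s", class_index = 1:2,
                            count_per_ml = c(300, 100))
  g <- tibble::tibble(class_index = 1:2, lower_um = d - 0.1,
                      upper_um = d + 0.1, midpoint_um = d,
                      width_um = 0.2)
  expect_equal(average_diameter(counts2, g)$d_av_um,
               (300 * 1.19 + 100 * 4) / 400)
  expect_equal((300 * 1.19 + 100 * 4) / 400, 1.8925)

  # bounded by the midpoint range
  withr::local_seed(3)
  rnd <- simulate_tep_counts(grid, -2, 1e4)
  dav <- average_diameter(rnd, grid)$d_av_um
  expect_gte(dav, min(grid$midpoint_um))
  expect_lte(dav, max(grid$midpoint_um))

  zeros <- tibble::tibble(sample_id = "s", class_index = 1:15,
                          count_per_ml = 0)
  expect_error(average_diameter(zeros, grid),
               class = "dustballast_fit_error")
})

test_that("volume concentration follows the spherical-volume formula and is additive", {
  # 1000 # mL^-1 at dp = 10 um -> (pi/6) * 1e3 * 1e3 * 1e-6 ppm
  g <- tibble::tibble(class_index = 1, lower_um = 8, upper_um = 12,
                      midpoint_um = 10, width_um = 4)
  counts <- tibble::tibble(sample_id = "s", class_index = 1,
                           count_per_ml = 1000)
  expect_equal(volume_concentration(counts, g)$cv_ppm,
               pi / 6 * 10^3 * 1000 * 1e-6)
  expect_equal(volume_concentration(counts, g)$cv_ppm, 0.5236,
               tolerance = 1e-4)

  grid <- build_size_grid(1, 135, 15)
  zeros <- tibble::tibble(sample_id = "s", class_index = 1:15,
                          count_per_ml = 0)
  expect_equal(volume_concentration(zeros, grid)$cv_ppm, 0)

  # splitting a sample's counts across two samples preserves total volume
  withr::local_seed(11)
  full <- simulate_tep_counts(grid, -2.2, 8e3, sample_id = "full")
  part <- dplyr::bind_rows(
    dplyr::mutate(full, sample_id = "a", count_per_ml = 0.3 * count_per_ml),
    dplyr::mutate(full, sample_id = "b", count_per_ml = 0.7 * count_per_ml)
  )
  expect_equal(sum(volume_concentration(part, grid)$cv_ppm),
               volume_concentration(full, grid)$cv_ppm)
})

test_that("counting-error SDs reproduce the published +/- values", {
  counts <- tibble::tibble(
    sample_id = c("T1.5", "T1", "empty"),
    class_index = 1,
    count_per_ml = c(14449, 10364, 0)
  )
  res <- abundance_with_error(counts, counting_error = 0.2)
  res <- res[match(c("T1.5", "T1", "empty"), res$sample_id), ]
  expect_equal(round(res$abundance_sd), c(2890, 2073, 0))
  # parameterized fraction
  res5 <- abundance_with_error(counts, counting_error = 0.05)
  expect_equal(res5$abundance_sd, 0.05 * res5$abundance)
})

test_that("tep_summary aggregates all per-sample statistics consistently", {
  grid <- build_size_grid()
  counts <- simulate_tep_timeseries(grid, seed = 5)
  s <- tep_summary(counts, grid)
  expect_equal(nrow(s), 8)
  expect_named(s, c("sample_id", "abundance", "abundance_sd", "delta", "k",
                    "r_squared", "n_bins_used", "d_av_um", "cv_ppm"))
  expect_equal(s$abundance_sd, 0.2 * s$abundance)
  expect_true(all(s$delta < 0))
  expect_true(all(s$cv_ppm > 0))
})

test_that("size spectrum plot builds without error", {
  grid <- build_size_grid()
  counts <- simulate_tep_counts(grid, -2.1, 1e4, seed = 2)
  p <- plot_size_spectrum(counts, grid)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
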