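#' Fit the lithogenic-ballast regression through the origin
#'
#' Fits the zero-intercept least-squares relationship
#' `POC flux = slope * lithogenic flux` across trap budgets. The slope is the
#' closed-form one-parameter solution `sum(x*y) / sum(x^2)` (in mg of organic
#' carbon exported per mg of lithogenic material); with no dust there is no
#' ballast-driven export, hence no intercept. The coefficient of
#' determination uses the centered convention
#' `r2 = 1 - RSS / sum((y - mean(y))^2)` with residuals taken from the origin
#' fit, and the slope's p-value comes from the one-parameter regression
#' t-test on `n - 1` degrees of freedom.
#'
#' Both fluxes must share a time basis (daily fluxes by default, as produced
#' by [trap_budget()]); because the model is proportional, rescaling both
#' axes by the same constant (e.g. daily versus experiment-integrated fluxes)
#' leaves the slope and r^2 unchanged.
#'
#' @param fluxes A data frame of flux pairs, one row per trap/experiment.
#' @param litho,poc Columns of `fluxes` holding the lithogenic and POC
#'   fluxes (tidy-eval; default `litho_flux_daily`, `poc_flux_daily`), both
#'   in mg m^-2 d^-1 (or any common basis).
#'
#' @return An object of class `ballast_fit` with elements `slope`,
#'   `std_error`, `t_value`, `p_value`, `r_squared`, `n_points`, and `data`
#'   (a tibble with per-point fitted values and residuals). Supports
#'   [tidy()], [glance()], `predict()`, `coef()` and [autoplot()].
#'
#' @examples
#' fit <- fit_ballast(chipie_flux_points())
#' fit
#' glance(fit)
#'
#' @export
fit_ballast <- function(fluxes, litho = litho_flux_daily,
                        poc = poc_flux_daily) {
  x <- dplyr::pull(fluxes, {{ litho }})
  y <- dplyr::pull(fluxes, {{ poc }})
  label <- if ("label" %in% names(fluxes)) fluxes$label else
    as.character(seq_along(x))
  if (length(x) < 2) {
    abort("the ballast fit needs at least 2 flux points.",
          class = "dustballast_fit_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    abort("fluxes must be finite and non-negative.",
          class = "dustballast_validation_error")
  }
  if (all(x == 0)) {
    abort("all lithogenic fluxes are zero; the slope is undefined.",
          class = "dustballast_fit_error")
  }
  n <- length(x)
  slope <- sum(x * y) / sum(x^2)
  fitted <- slope * x
  residual <- y - fitted
  rss <- sum(residual^2)
  tss <- sum((y - mean(y))^2)
  # a degenerate point cloud (all y identical) has zero centered TSS; the
  # fit is then either perfect (zero residuals) or meaningless
  r_squared <- if (tss > 0) {
    1 - rss / tss
  } else if (rss <= 1e-12 * max(sum(y^2), 1)) 1 else NaN
  df <- n - 1
  std_error <- sqrt(rss / df / sum(x^2))
  t_value <- slope / std_error
  p_value <- 2 * pt(-abs(t_value), df)
  structure(
    list(
      slope = slope, std_error = std_error, t_value = t_value,
      p_value = p_value, r_squared = r_squared, n_points = n,
      df_residual = df,
      data = tibble::tibble(label = label, litho_flux = x, poc_flux = y,
                            fitted = fitted, residual = residual)
    ),
    class = "ballast_fit"
  )
}

#' @export
print.ballast_fit <- function(x, ...) {
  cat("Zero-intercept ballast regression: POC flux = slope * lithogenic flux\n")
  cat(sprintf("  slope:   %.5f (SE %.5f, t = %.2f, p = %.2g, df = %d)\n",
              x$slope, x$std_error, x$t_value, x$p_value, x$df_residual))
  cat(sprintf("  r^2:     %.3f (centered convention)\n", x$r_squared))
  cat(sprintf("  points:  %d\n", x$n_points))
  invisible(x)
}

#' @export
coef.ballast_fit <- function(object, ...) {
  c(slope = object$slope)
}

#' Tidy a ballast fit
#'
#' @param x A `ballast_fit` object.
#' @param ... Unused.
#'
#' @return A one-row tibble with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#'
#' @exportS3Method generics::tidy
tidy.ballast_fit <- function(x, ...) {
  tibble::tibble(
    term = "litho_flux", estimate = x$slope, std.error = x$std_error,
    statistic = x$t_value, p.value = x$p_value
  )
}

#' Glance at a ballast fit
#'
#' @param x A `ballast_fit` object.
#' @param ... Unused.
#'
#' @return A one-row tibble with `r.squared`, `p.value`, `df.residual`,
#'   `nobs`.
#'
#' @exportS3Method generics::glance
glance.ballast_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, p.value = x$p_value,
    df.residual = x$df_residual, nobs = x$n_points
  )
}

#' @export
predict.ballast_fit <- function(object, litho_flux, ...) {
  predict_poc_litho(object, litho_flux)
}

#' Predict the lithogenic-associated POC flux for a dust flux
#'
#' Applies the fitted proportionality to a lithogenic flux, on whatever time
#' basis the input uses (the model is linear, so daily in gives daily out,
#' event-integrated in gives event-integrated out).
#'
#' @param fit A `ballast_fit` object (or a bare numeric slope).
#' @param litho_flux Lithogenic flux (same mass/area units as the fit data).
#'
#' @return Predicted POC_litho flux, same units as `litho_flux` times the
#'   dimensionless slope.
#'
#' @examples
#' fit <- fit_ballast(chipie_flux_points())
#' # a 22 g m^-2 extreme dust event:
#' predict_poc_litho(fit, 22000)  # ~270 mg m^-2, i.e. ~0.27 g m^-2
#'
#' @export
predict_poc_litho <- function(fit, litho_flux) {
  slope <- if (inherits(fit, "ballast_fit")) fit$slope else fit
  if (any(!is.finite(litho_flux)) || any(litho_flux < 0)) {
    abort("`litho_flux` must be non-negative.",
          class = "dustballast_validation_error")
  }
  slope * litho_flux
}

#' Contribution of lithogenic-associated POC to a total POC export
#'
#' @param poc_litho POC flux attributed to lithogenic ballasting (any unit).
#' @param total_poc Total POC export in the same unit; must be positive.
#'
#' @return Percentage contribution, `100 * poc_litho / total_poc`.
#'
#' @examples
#' contribution_fraction(0.27, 0.8)  # ~34% of an event-scale export
#'
#' @export
contribution_fraction <- function(poc_litho, total_poc) {
  if (any(!is.finite(total_poc)) || any(total_poc <= 0)) {
    abort("`total_poc` must be strictly positive.",
          class = "dustballast_validation_error")
  }
  100 * poc_litho / total_poc
}

#' Plot a ballast fit
#'
#' Scatter of POC flux against lithogenic flux with the fitted
#' through-origin line and its annotation.
#'
#' @param object A `ballast_fit` object.
#' @param ... Unused.
#'
#' @return A ggplot object.
#'
#' @exportS3Method ggplot2::autoplot
autoplot.ballast_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(.data$litho_flux, .data$poc_flux)) +
    ggplot2::geom_abline(intercept = 0, slope = object$slope,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression("lithogenic flux" ~ (mg ~ m^-2 ~ d^-1)),
      y = expression(POC[litho] ~ "flux" ~ (mg ~ m^-2 ~ d^-1)),
      subtitle = sprintf("slope = %.3f, r² = %.3f, p = %.1g",
                         object$slope, object$r_squared, object$p_value)
    ) +
    ggplot2::expand_limits(x = 0, y = 0) +
    ggplot2::theme_minimal()
}
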