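#' Build a logarithmic particle size-class grid
#'
#' Constructs the diameter classes used to bin TEP (transparent exopolymer
#' particle) counts. Class boundaries follow a geometric progression between
#' `d_min` and `d_max`, so every class spans the same factor in diameter:
#' consecutive boundaries differ by `(d_max/d_min)^(1/n_classes)`. The default
#' grid is the 15 logarithmic classes between 1 and 135 um used for
#' microscopy-based TEP sizing.
#'
#' @param d_min,d_max Lower and upper diameter limits of the grid, in um.
#'   Must satisfy `0 < d_min < d_max`.
#' @param n_classes Number of size classes (at least 1).
#' @param midpoint How the representative ("mid-point") diameter of each class
#'   is computed: `"arithmetic"` (default) uses the mean of the class
#'   boundaries, `"geometric"` their geometric mean. Both lie strictly inside
#'   the class.
#'
#' @return A tibble with one row per class and columns `class_index`,
#'   `lower_um`, `upper_um`, `midpoint_um`, `width_um`.
#'
#' @examples
#' grid <- build_size_grid()
#' grid
#' # common boundary ratio:
#' unique(round(grid$upper_um / grid$lower_um, 6))
#'
#' @export
build_size_grid <- function(d_min = 1, d_max = 135, n_classes = 15,
                            midpoint = c("arithmetic", "geometric")) {
  midpoint <- match.arg(midpoint)
  if (!is.numeric(d_min) || !is.numeric(d_max) || length(d_min) != 1 ||
      length(d_max) != 1 || !is.finite(d_min) || !is.finite(d_max) ||
      d_min <= 0 || d_max <= d_min) {
    abort("`d_min` and `d_max` must satisfy 0 < d_min < d_max.",
          class = "dustballast_grid_error")
  }
  if (!is.numeric(n_classes) || length(n_classes) != 1 ||
      n_classes < 1 || n_classes != round(n_classes)) {
    abort("`n_classes` must be a positive whole number.",
          class = "dustballast_grid_error")
  }
  n_classes <- as.integer(n_classes)
  boundaries <- d_min * (d_max / d_min)^(seq(0L, n_classes) / n_classes)
  # guard against floating-point drift at the endpoints
  boundaries[1] <- d_min
  boundaries[n_classes + 1] <- d_max
  lower <- boundaries[-(n_classes + 1)]
  upper <- boundaries[-1]
  mid <- switch(midpoint,
                arithmetic = (lower + upper) / 2,
                geometric  = sqrt(lower * upper))
  tibble::tibble(
    class_index = seq_len(n_classes),
    lower_um    = lower,
    upper_um    = upper,
    midpoint_um = mid,
    width_um    = upper - lower
  )
}

# shared validation for count tables against a grid
check_counts <- function(counts, grid, call = rlang::caller_env()) {
  required <- c("sample_id", "class_index", "count_per_ml")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort(paste0("`counts` is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dustballast_shape_error", call = call)
  }
  if (any(!is.finite(counts$count_per_ml)) || any(counts$count_per_ml < 0)) {
    abort("`count_per_ml` must be finite and non-negative.",
          class = "dustballast_shape_error", call = call)
  }
  bad <- counts |>
    dplyr::count(.data$sample_id, name = "n_rows") |>
    dplyr::filter(.data$n_rows != nrow(grid))
  if (nrow(bad) > 0 ||
      !all(counts$class_index %in% grid$class_index)) {
    abort(
      paste0("each sample must have exactly one row per grid class (",
             nrow(grid), " classes)."),
      class = "dustballast_shape_error", call = call
    )
  }
  invisible(counts)
}
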