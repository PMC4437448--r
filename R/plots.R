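# ggplot2 graphics for the main result types.

#' Plot a T2 map slice
#'
#' @param object A `t2_map` from [fit_t2_map()].
#' @param slice Slice index to display (default: middle slice).
#' @param what One of `"t2"`, `"s0"`, `"r_squared"`.
#' @param ... Unused.
#' @return A ggplot object (invalid voxels are blank).
#' @exportS3Method ggplot2::autoplot
autoplot.t2_map <- function(object, slice = NULL,
                            what = c("t2", "s0", "r_squared"), ...) {
  what <- match.arg(what)
  if (is.null(slice)) slice <- ceiling(dim(object$t2)[3] / 2)
  df <- tidy(object, valid_only = FALSE) |>
    dplyr::filter(.data$slice == .env$slice)
  lab <- c(t2 = "T2 (ms)", s0 = "S0", r_squared = "R²")[[what]]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey10", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Slice %d (%s fit)", slice, object$method),
                  x = "x (voxel)", y = "y (voxel)") +
    ggplot2::theme_minimal()
}

#' Plot one voxel's echo-train decay and fit
#'
#' @param signal Signal values, one per echo.
#' @param echo_times Echo times (ms).
#' @param fit Optional one-row fit tibble from [fit_t2_voxel()] to overlay.
#' @return A ggplot object.
#' @export
plot_decay <- function(signal, echo_times, fit = NULL) {
  df <- tibble::tibble(te = echo_times, signal = signal)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$te, .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "TE (ms)", y = "Signal") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$valid)) {
    curve <- tibble::tibble(
      te = seq(min(echo_times), max(echo_times), length.out = 200))
    curve$signal <- fit$s0 * exp(-curve$te / fit$t2)
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("T2 = %.1f ms, R² = %.3f",
                                       fit$t2, fit$r_squared))
  }
  p
}

#' Group comparison plot for one endpoint
#'
#' Box-and-jitter display of a per-animal endpoint by treatment group, the
#' standard figure for two-arm MCAO readouts.
#'
#' @param data Per-animal results tibble (e.g. from [analyze_cohort()]).
#' @param endpoint Endpoint column name.
#' @param group_col Grouping column (default `"group"`).
#' @return A ggplot object.
#' @export
plot_endpoint <- function(data, endpoint, group_col = "group") {
  if (!endpoint %in% names(data)) {
    abort(paste0("Endpoint column '", endpoint, "' not found."),
          class = "strokevol_validation_error")
  }
  ggplot2::ggplot(data, ggplot2::aes(.data[[group_col]],
                                     .data[[endpoint]],
                                     colour = .data[[group_col]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5,
                          colour = "grey40") +
    ggplot2::geom_jitter(width = 0.12, size = 2, alpha = 0.8) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = endpoint) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
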