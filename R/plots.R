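#' Plot a directional signal decay with fitted models
#'
#' Shows the measured signal fractions against b-value on a log scale,
#' optionally overlaying fitted mono-, stretched-, kurtosis- and
#' bi-exponential curves.
#'
#' @param decay a [directional_decay()].
#' @param fits optional named list of fit results, with any of the names
#'   `monoexp`, `stretched`, `kurtosis`, `biexp` holding the matching fit
#'   tibbles.
#' @return A ggplot object.
#' @export
plot_decay <- function(decay, fits = NULL) {
  bgrid <- seq(min(decay$b), max(decay$b), length.out = 200)
  curves <- list()
  if (!is.null(fits$monoexp)) {
    curves$`mono-exponential` <- exp(-bgrid * fits$monoexp$D_app)
  }
  if (!is.null(fits$stretched)) {
    curves$`stretched-exponential` <-
      exp(-(bgrid^fits$stretched$alpha) * fits$stretched$D_st)
  }
  if (!is.null(fits$kurtosis)) {
    f <- fits$kurtosis
    curves$kurtosis <- exp(-bgrid * f$D_app +
                             bgrid^2 * f$D_app^2 * f$K_app / 6)
  }
  if (!is.null(fits$biexp)) {
    f <- fits$biexp
    curves$`bi-exponential` <- f$v_f * exp(-f$D_f * bgrid) +
      f$v_s * exp(-f$D_s * bgrid)
  }
  curve_df <- if (length(curves) > 0) {
    dplyr::bind_rows(lapply(names(curves), function(nm) {
      tibble::tibble(b = bgrid, sfrac = curves[[nm]], model = nm)
    }))
  } else NULL
  p <- ggplot2::ggplot(decay, ggplot2::aes(x = .data$b, y = .data$sfrac)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(b ~ (s/mm^2)), y = "S(b) / S(0)") +
    ggplot2::theme_minimal()
  if (!is.null(curve_df)) {
    p <- p + ggplot2::geom_line(
      data = curve_df,
      ggplot2::aes(x = .data$b, y = .data$sfrac, colour = .data$model)
    )
  }
  p
}

#' Column plot of ROI summaries by group
#'
#' Group means with standard-deviation error bars, faceted by index:
#' the standard presentation of per-ROI derived indices across tissue
#' groups.
#'
#' @param summaries a tibble of ROI summaries (from [aggregate_roi()] or
#'   `run_pipeline()$roi_summaries`).
#' @param indices optional character vector restricting the indices shown.
#' @return A ggplot object.
#' @export
plot_group_columns <- function(summaries, indices = NULL) {
  if (!is.null(indices)) {
    summaries <- summaries[summaries$index_name %in% indices, ]
  }
  agg <- summaries |>
    dplyr::group_by(.data$index_name, .data$group) |>
    dplyr::summarise(m = mean(.data$mean), s = sd(.data$mean),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$group, y = .data$m,
                                    fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m - .data$s,
                                        ymax = .data$m + .data$s),
                           width = 0.3) +
    ggplot2::facet_wrap(~index_name, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "ROI mean") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Barycentric (3P) plot of Westin shape measures
#'
#' Projects (C_L, C_P, C_S) triples into the barycentric triangle used to
#' compare tensor shape distributions between groups.
#'
#' @param shapes a tibble with columns `C_L`, `C_P`, `C_S` and optionally
#'   `group`.
#' @return A ggplot object.
#' @export
plot_westin_triangle <- function(shapes) {
  # vertices: C_L at top, C_P bottom-left, C_S bottom-right
  x <- shapes$C_P * 0 + shapes$C_S * 1 + shapes$C_L * 0.5
  y <- shapes$C_L * sqrt(3) / 2
  df <- tibble::tibble(x = x, y = y,
                       group = if ("group" %in% names(shapes)) {
                         shapes$group
                       } else "all")
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5),
                      y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("C[P]", "C[S]", "C[L]"), parse = TRUE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Column-plot view of a pipeline report
#'
#' @param object a `microstructure_report` from [run_pipeline()].
#' @param indices optional character vector restricting the indices shown.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.microstructure_report <- function(object, indices = NULL, ...) {
  plot_group_columns(object$roi_summaries, indices = indices)
}
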