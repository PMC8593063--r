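#' Summarise an index map over a region of interest
#'
#' Mean and standard deviation of a per-voxel index over the unflagged
#' voxels of one slice-level ROI (the observational unit of the group
#' analysis: one ROI per slice, several slices per sample).
#'
#' @param index_map 3-D numeric array of a derived index.
#' @param roi_mask logical 3-D array marking the ROI.
#' @param group tissue group label.
#' @param sample_id,slice_id identifiers of the sample and slice.
#' @param index_name name of the index.
#' @param flag_mask optional logical 3-D array of failed-fit voxels to
#'   exclude.
#' @return A one-row tibble (`roi_summary`) with columns `group`,
#'   `sample_id`, `slice_id`, `index_name`, `mean`, `sd`, `n_voxels`.
#' @export
aggregate_roi <- function(index_map, roi_mask, group, sample_id, slice_id,
                          index_name = "index", flag_mask = NULL) {
  if (!any(roi_mask)) stop_input("ROI mask is empty")
  keep <- roi_mask
  if (!is.null(flag_mask)) keep <- keep & !flag_mask
  vals <- index_map[keep]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    stop_input("no usable voxels remain in the ROI after exclusions")
  }
  tibble::tibble(
    group = group, sample_id = sample_id, slice_id = slice_id,
    index_name = index_name,
    mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
    n_voxels = length(vals)
  )
}

#' One-way ANOVA with Tukey post-hoc comparison of tissue groups
#'
#' Compares slice-level ROI means across groups with a one-way analysis of
#' variance followed by Tukey honest-significant-difference tests over all
#' group pairs. Differences are declared significant at `alpha` (default
#' 0.05).
#'
#' @param data a data frame with one observation per ROI.
#' @param value name of the column holding the ROI means.
#' @param group name of the grouping column.
#' @param index_name label for the compared index.
#' @param alpha significance level.
#' @return An object of class `group_comparison`: a list with the index
#'   name, `F` statistic, degrees of freedom, `p` value, `significant`
#'   flag and a `posthoc` tibble of pairwise Tukey-adjusted comparisons.
#' @export
one_way_anova <- function(data, value = "mean", group = "group",
                          index_name = "index", alpha = 0.05) {
  y <- data[[value]]
  grp <- factor(data[[group]])
  if (nlevels(grp) < 2) stop_input("need at least 2 groups")
  if (any(table(grp) < 2)) {
    stop_input("every group needs at least 2 observations")
  }
  fit <- aov(y ~ grp)
  tab <- anova(fit)
  tuk <- TukeyHSD(fit)$grp
  posthoc <- tibble::tibble(
    contrast = rownames(tuk),
    diff = tuk[, "diff"],
    lwr = tuk[, "lwr"],
    upr = tuk[, "upr"],
    p_adj = tuk[, "p adj"],
    significant = tuk[, "p adj"] < alpha
  )
  structure(
    list(
      index_name = index_name,
      F = tab[["F value"]][1],
      df = c(tab[["Df"]][1], tab[["Df"]][2]),
      p = tab[["Pr(>F)"]][1],
      significant = tab[["Pr(>F)"]][1] < alpha,
      alpha = alpha,
      posthoc = posthoc
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison '%s'>  F(%d, %d) = %.4g, p = %.4g%s\n",
              x$index_name, x$df[1], x$df[2], x$F, x$p,
              if (x$significant) " *" else ""))
  print(x$posthoc)
  invisible(x)
}

#' Tidy a group comparison
#'
#' `tidy()` returns the pairwise Tukey post-hoc table; `glance()` returns
#' the one-row ANOVA summary.
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  dplyr::mutate(x$posthoc, index_name = x$index_name, .before = 1)
}

#' @rdname tidy.group_comparison
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    index_name = x$index_name, statistic = x$F,
    df = x$df[1], df_residual = x$df[2], p_value = x$p,
    significant = x$significant
  )
}
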