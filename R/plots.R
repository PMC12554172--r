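#' Heatmap of parent-normalized substitution effects
#'
#' Position x residue tile map of mean percent-of-parent signal. The fill
#' scale is fixed to 0-200% with overflow binning: cells above 200%
#' (strong enhancements) are shown at the top color and marked in the
#' legend, so enhancement and loss stay readable on one scale.
#'
#' @param matrix A `normalized_matrix` from [normalize_to_parent()].
#' @param what `"mean"` (default) or `"sd"`.
#' @return A ggplot object.
#' @export
plot_substitution_heatmap <- function(matrix, what = c("mean", "sd")) {
  what <- match.arg(what)
  d <- as_tibble(matrix) |>
    mutate(
      value = if (what == "mean") .data$mean_pct else .data$sd_pct,
      shown = pmin(.data$value, 200),
      residue = factor(.data$residue, levels = rev(amino_acids))
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$position), y = .data$residue, fill = .data$shown
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(
      low = "black", mid = "white", high = "firebrick",
      midpoint = 100, limits = c(0, 200),
      name = if (what == "mean") "% of parent\n(capped 200)" else "sd (pp)"
    ) +
    ggplot2::labs(x = "Position", y = "Substituted residue") +
    ggplot2::theme_minimal()
}

#' Contact-frequency heatmap
#'
#' Receptor residues on the x-axis, peptide residues on the y-axis, tile
#' fill from 0 (never in contact, dark) to 1 (continuous contact, light).
#'
#' @param cmap A `contact_map` from [contact_frequency()].
#' @return A ggplot object.
#' @export
plot_contact_map <- function(cmap) {
  ggplot2::ggplot(as_tibble(cmap), ggplot2::aes(
    x = factor(.data$receptor_resno), y = factor(.data$peptide_resno),
    fill = .data$frequency
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "black", high = "lightyellow", limits = c(0, 1),
      name = "Contact\nfrequency"
    ) +
    ggplot2::labs(x = "Receptor residue", y = "Peptide residue") +
    ggplot2::theme_minimal()
}

#' RMSD stability plot over trials
#'
#' Mean RMSD line with a band of +/- one standard deviation (square root
#' of the across-trial variance) around it.
#'
#' @param aggregate Output of [aggregate_rmsd()].
#' @return A ggplot object.
#' @export
plot_rmsd <- function(aggregate) {
  d <- aggregate |> mutate(sd = sqrt(.data$var_rmsd_nm2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$mean_rmsd_nm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_rmsd_nm - .data$sd,
        ymax = .data$mean_rmsd_nm + .data$sd
      ),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Frame", y = "RMSD (nm)") +
    ggplot2::theme_minimal()
}

#' @method autoplot saturation_fit
#' @export
autoplot.saturation_fit <- function(object, ...) {
  conc <- object$data$concentration_uM
  grid <- tibble(
    concentration_uM = exp(seq(log(min(conc)), log(max(conc)), length.out = 200))
  )
  grid$ru <- predict(object, grid)
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$concentration_uM, y = .data$ru_specific)
  ) +
    ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$ru), color = "steelblue"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$kd, linetype = "dotted", color = "grey40"
    ) +
    ggplot2::geom_hline(
      yintercept = object$bmax / 2, linetype = "dotted", color = "grey70"
    ) +
    ggplot2::annotate(
      "text", x = object$kd, y = max(object$data$ru_specific),
      label = sprintf("Kd = %.3g uM", object$kd), hjust = -0.1, size = 3
    ) +
    ggplot2::labs(x = "Analyte concentration (uM)", y = "Specific response (RU)") +
    ggplot2::theme_minimal()
}

#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  t_grid <- tibble(
    timepoint_min = seq(0, max(object$data$timepoint_min), length.out = 200)
  )
  t_grid$abundance_pct <- if (!is.na(object$plateau)) {
    object$plateau + (100 - object$plateau) * exp(-object$k * t_grid$timepoint_min)
  } else {
    100 * exp(-object$k * t_grid$timepoint_min)
  }
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$timepoint_min, y = .data$abundance_pct)
  ) +
    ggplot2::geom_line(data = t_grid, color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::annotate(
      "text", x = max(object$data$timepoint_min) * 0.7, y = 90,
      label = sprintf("t[1/2] == %.3g ~ min", object$t_half),
      parse = TRUE, size = 3
    ) +
    ggplot2::labs(x = "Time after translation arrest (min)", y = "Abundance (% of t = 0)") +
    ggplot2::theme_minimal()
}
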