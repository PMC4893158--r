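#' Plot a Ripley curve, optionally with its CSR envelope
#'
#' Shows `L(r) - r` against `r`; values above the envelope indicate
#' clustering at that scale.
#'
#' @param object A `ripley_curve` from [ripley_k()].
#' @param envelope Optional `csr_envelope` from [csr_envelope()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ripley_curve
#' @export
autoplot.ripley_curve <- function(object, envelope = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r,
                                            y = .data$l_minus_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "r (nm)", y = "L(r) - r (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    p <- p + ggplot2::geom_ribbon(
      data = envelope,
      ggplot2::aes(x = .data$r, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.25)
  }
  p
}

#' Plot an interpolated local-L cluster map
#'
#' @param object An `nc_cluster_map` from [build_cluster_map()].
#' @param threshold Optional threshold (numeric or `nc_threshold`) drawn as a
#'   contour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nc_cluster_map
#' @export
autoplot.nc_cluster_map <- function(object, threshold = NULL, ...) {
  gs <- object$grid_step
  df <- expand.grid(ix = seq_len(nrow(object$values)),
                    iy = seq_len(ncol(object$values)))
  df$x <- (df$ix - 0.5) * gs
  df$y <- (df$iy - 0.5) * gs
  df$l <- as.numeric(object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$l)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = sprintf("L(%g)", object$r0)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    if (inherits(threshold, "nc_threshold")) threshold <- threshold$threshold
    p <- p + ggplot2::geom_contour(
      ggplot2::aes(z = .data$l), breaks = threshold, colour = "white",
      linewidth = 0.3)
  }
  p
}

#' Plot observed versus null association fractions by size tertile
#'
#' Bars are the observed shares of associated receptor clusters per tertile;
#' points with ranges are the randomization-null mean and central 95% band.
#'
#' @param object A `size_effect` comparison from [size_effect_summary()], or
#'   an `sted_analysis`.
#' @param null The `null_distribution` (needed for the band when `object` is
#'   a plain tibble).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_size_effect <- function(object, null = NULL, ...) {
  if (inherits(object, "sted_analysis")) {
    null <- object$null
    object <- object$size_effect
  }
  df <- object
  if (!is.null(null)) {
    qs <- vapply(c("frac_small", "frac_medium", "frac_large"),
                 function(col) stats::quantile(null[[col]],
                                               c(0.025, 0.975), na.rm = TRUE),
                 numeric(2))
    df$null_lo <- qs[1, ]
    df$null_hi <- qs[2, ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$tertile,
                                        .data$observed_frac)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_frac), size = 2) +
    ggplot2::labs(x = "receptor cluster size tertile",
                  y = "fraction of associated clusters") +
    ggplot2::theme_minimal()
  if (!is.null(null)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$null_lo, ymax = .data$null_hi), width = 0.2)
  }
  p
}
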