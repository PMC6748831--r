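#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_ribbon
#'   geom_histogram geom_hline geom_raster labs theme_minimal
#'   scale_fill_viridis_c coord_equal
#' @export
ggplot2::autoplot

#' Plot a CBC histogram
#'
#' The familiar 0.1-binned histogram of the per-localization colocalization
#' parameter from -1 (segregated) to +1 (colocalized).
#'
#' @param object A `cbc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cbc_result
#' @export
autoplot.cbc_result <- function(object, ...) {
  h <- attr(object, "histogram")
  ggplot(h, aes(x = .data$bin_mid, y = .data$count)) +
    geom_col(width = 0.09, fill = "grey30") +
    labs(x = "colocalization parameter", y = "localizations") +
    theme_minimal()
}

#' Plot an angular-averaged cross-correlogram
#'
#' C(r) with the CSR reference level at 1 and a +/- 3 uncertainty ribbon.
#'
#' @param object A `cross_correlogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_correlogram
#' @export
autoplot.cross_correlogram <- function(object, ...) {
  ggplot(object, aes(x = .data$r_nm, y = .data$C)) +
    geom_ribbon(aes(ymin = .data$C - 3 * .data$uncertainty,
                    ymax = .data$C + 3 * .data$uncertainty),
                fill = "grey80") +
    geom_line() +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = "r (nm)", y = "C(r)") +
    theme_minimal()
}

#' Plot the vesicle diameter distribution
#'
#' @param object A `vesicle_set`.
#' @param binwidth Histogram bin width in nm.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot vesicle_set
#' @export
autoplot.vesicle_set <- function(object, binwidth = 10, ...) {
  ggplot(object, aes(x = .data$diameter_nm)) +
    geom_histogram(binwidth = binwidth, fill = "grey30", colour = "white") +
    labs(x = "vesicle diameter (nm)", y = "count") +
    theme_minimal()
}

#' Plot an estimated drift trajectory
#'
#' @param object A `drift_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot drift_trajectory
#' @export
autoplot.drift_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("dx_nm", "dy_nm"),
                              names_to = "axis", values_to = "nm")
  ggplot(long, aes(x = .data$knot_frame, y = .data$nm,
                   colour = .data$axis)) +
    geom_line() +
    labs(x = "frame", y = "displacement (nm)") +
    theme_minimal()
}

#' Plot a rendered super-resolution image
#'
#' @param object A `rendered_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rendered_image
#' @export
autoplot.rendered_image <- function(object, ...) {
  img <- object$intensity
  df <- expand.grid(col = seq_len(ncol(img)), row = seq_len(nrow(img)))
  df$value <- as.numeric(t(img))
  df$x_nm <- object$origin_nm[1] + (df$col - 0.5) * object$pixel_size_nm
  df$y_nm <- object$origin_nm[2] + (df$row - 0.5) * object$pixel_size_nm
  ggplot(df, aes(x = .data$x_nm, y = .data$y_nm, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", fill = "intensity") +
    theme_minimal()
}
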