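#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MESF calibration fit
#'
#' @param x An `mesf_calibration`.
#' @param ... Unused.
#' @return One row per coefficient of the log-log fit.
#' @method tidy mesf_calibration
#' @export
tidy.mesf_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.mesf_calibration
#' @method glance mesf_calibration
#' @export
glance.mesf_calibration <- function(x, ...) {
  tibble(r_squared = x$r_squared, blank = x$blank,
         intensity_min = x$intensity_range[1],
         intensity_max = x$intensity_range[2])
}

#' Tidy a fitted channel transform
#'
#' @param x A `channel_transform`.
#' @param ... Unused.
#' @return One row per polynomial coefficient and axis.
#' @method tidy channel_transform
#' @export
tidy.channel_transform <- function(x, ...) {
  tibble(axis = rep(c("x", "y"), each = length(x$coef_x)),
         term = rep(colnames(poly_basis(0, 0, x$order)), 2),
         estimate = c(unname(x$coef_x), unname(x$coef_y)))
}

#' @rdname tidy.channel_transform
#' @method glance channel_transform
#' @export
glance.channel_transform <- function(x, ...) {
  tibble(order = x$order, rms_nm = x$rms_nm, n_pairs = x$n_pairs)
}

#' Summaries of colocalization results
#'
#' @param x A `cbc_result`, `cross_correlogram` or `nnd_result`.
#' @param ... Unused.
#' @return `glance` gives one summary row; `tidy` the per-unit values.
#' @method glance cbc_result
#' @export
glance.cbc_result <- function(x, ...) {
  tibble(mean_value = mean(x$value), median_value = median(x$value),
         n_evaluated = nrow(x), n_excluded = attr(x, "n_excluded"))
}

#' @rdname glance.cbc_result
#' @method glance cross_correlogram
#' @export
glance.cross_correlogram <- function(x, ...) {
  tibble(peak_r_nm = xcorr_peak(x), peak_C = max(x$C, na.rm = TRUE),
         n_bins = nrow(x))
}

#' @rdname glance.cbc_result
#' @method glance nnd_result
#' @export
glance.nnd_result <- function(x, ...) {
  tibble(median_nnd_nm = median(x$dist_nm), mean_nnd_nm = mean(x$dist_nm),
         n = nrow(x))
}
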