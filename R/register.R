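#' Fit a polynomial channel transform from fiducial pairs
#'
#' Least-squares polynomial mapping of moving-channel coordinates onto the
#' reference channel (the 640 nm channel in a three-color acquisition). Order
#' 1 is affine; order 2 adds quadratic terms. The pair count must be at least
#' the number of coefficients per axis.
#'
#' @param pairs Tibble with columns `x_mov`, `y_mov`, `x_ref`, `y_ref` (nm),
#'   one row per fiducial.
#' @param order Polynomial order (>= 1, default 1).
#' @return A `channel_transform`: list with coefficient vectors per axis, the
#'   order, and the fit residual RMS in nm.
#' @export
fit_channel_transform <- function(pairs, order = 1L) {
  assert_cols(pairs, c("x_mov", "y_mov", "x_ref", "y_ref"), "pairs")
  if (order < 1) abort("`order` must be >= 1")
  n_coef <- (order + 1) * (order + 2) / 2
  if (nrow(pairs) < n_coef) {
    abort(sprintf("need at least %d fiducial pairs for order %d", n_coef,
                  order))
  }
  if (anyDuplicated(pairs[, c("x_ref", "y_ref")])) {
    abort("duplicate reference fiducial positions")
  }
  basis <- poly_basis(pairs$x_mov, pairs$y_mov, order)
  fx <- stats::lm.fit(basis, pairs$x_ref)
  fy <- stats::lm.fit(basis, pairs$y_ref)
  if (any(is.na(fx$coefficients)) || any(is.na(fy$coefficients))) {
    abort("degenerate fiducial geometry: transform is underdetermined")
  }
  rms <- sqrt(mean(fx$residuals^2 + fy$residuals^2))
  structure(list(order = as.integer(order),
                 coef_x = fx$coefficients, coef_y = fy$coefficients,
                 rms_nm = rms, n_pairs = nrow(pairs)),
            class = "channel_transform")
}

# Polynomial design matrix in graded-lexicographic term order.
poly_basis <- function(x, y, order) {
  cols <- list()
  nms <- character(0)
  for (deg in 0:order) for (i in 0:deg) {
    cols[[length(cols) + 1L]] <- x^(deg - i) * y^i
    nms <- c(nms, sprintf("x%dy%d", deg - i, i))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

transform_xy <- function(transform, x, y) {
  basis <- poly_basis(x, y, transform$order)
  list(x = drop(basis %*% transform$coef_x),
       y = drop(basis %*% transform$coef_y))
}

# Numerically invert the transform per point by Newton iteration with the
# analytic polynomial Jacobian (exact in one step for affine transforms).
invert_xy <- function(transform, x, y, tol = 1e-10, max_iter = 50L) {
  gx <- x; gy <- y
  for (it in seq_len(max_iter)) {
    f <- transform_xy(transform, gx, gy)
    rx <- f$x - x; ry <- f$y - y
    if (max(abs(rx), abs(ry)) < tol) break
    J <- poly_jacobian(transform, gx, gy)
    det <- J$dxdx * J$dydy - J$dxdy * J$dydx
    gx <- gx - ( J$dydy * rx - J$dxdy * ry) / det
    gy <- gy - (-J$dydx * rx + J$dxdx * ry) / det
  }
  list(x = gx, y = gy)
}

poly_jacobian <- function(transform, x, y) {
  ord <- transform$order
  dxdx <- dxdy <- dydx <- dydy <- numeric(length(x))
  k <- 0L
  for (deg in 0:ord) for (i in 0:deg) {
    k <- k + 1L
    px <- deg - i; py <- i
    bx <- if (px > 0) px * x^(px - 1) * y^py else 0
    by <- if (py > 0) x^px * py * y^(py - 1) else 0
    dxdx <- dxdx + transform$coef_x[k] * bx
    dxdy <- dxdy + transform$coef_x[k] * by
    dydx <- dydx + transform$coef_y[k] * bx
    dydy <- dydy + transform$coef_y[k] * by
  }
  list(dxdx = dxdx, dxdy = dxdy, dydx = dydx, dydy = dydy)
}

#' Apply (or invert) a channel transform on a localization table
#'
#' Maps `x_nm`, `y_nm` through the fitted polynomial; channel labels and row
#' count are unchanged. With `inverse = TRUE` the inverse mapping is solved
#' per point by Newton iteration.
#'
#' @param table Localization tibble.
#' @param transform A `channel_transform`.
#' @param inverse Apply the inverse mapping.
#' @param guard_nm Optional c(xmin, xmax, ymin, ymax); points mapping outside
#'   it are counted in the `n_outside_guard` attribute with a warning.
#' @return The transformed tibble.
#' @export
apply_transform <- function(table, transform, inverse = FALSE,
                            guard_nm = NULL) {
  assert_cols(table, c("x_nm", "y_nm"), "table")
  f <- if (inverse) invert_xy(transform, table$x_nm, table$y_nm)
       else transform_xy(transform, table$x_nm, table$y_nm)
  out <- table
  out$x_nm <- f$x; out$y_nm <- f$y
  if (!is.null(guard_nm)) {
    n_out <- sum(f$x < guard_nm[1] | f$x > guard_nm[2] |
                 f$y < guard_nm[3] | f$y > guard_nm[4])
    if (n_out > 0) {
      warn(sprintf("%d point(s) mapped outside the guard region", n_out))
    }
    attr(out, "n_outside_guard") <- n_out
  }
  keep_attrs(out, table)
}

#' Build fiducial pairs from two channels' fiducial localizations
#'
#' Averages each fiducial's localizations per channel over frames and matches
#' moving to reference beads by nearest neighbor.
#'
#' @param moving,reference Fiducial localization tibbles (`x_nm`, `y_nm`,
#'   optionally `fiducial`).
#' @param max_dist_nm Maximum pairing distance.
#' @return A pairs tibble suitable for [fit_channel_transform()].
#' @export
match_fiducials <- function(moving, reference, max_dist_nm = 500) {
  avg <- function(tb) {
    if ("fiducial" %in% names(tb)) {
      summarise(group_by(tb, .data$fiducial),
                x = mean(.data$x_nm), y = mean(.data$y_nm), .groups = "drop")
    } else tibble(fiducial = seq_len(nrow(tb)), x = tb$x_nm, y = tb$y_nm)
  }
  mv <- avg(moving); rf <- avg(reference)
  d2 <- pdist2(mv$x, mv$y, rf$x, rf$y)
  j <- apply(d2, 1L, which.min)
  keep <- sqrt(d2[cbind(seq_len(nrow(mv)), j)]) <= max_dist_nm
  tibble(x_mov = mv$x[keep], y_mov = mv$y[keep],
         x_ref = rf$x[j[keep]], y_ref = rf$y[j[keep]])
}

#' Serialize / restore a channel transform as structured text (JSON)
#'
#' @param transform A `channel_transform`.
#' @param path Output file.
#' @return `write_transform` returns `path` invisibly; `read_transform` the
#'   restored transform.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass(transform), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$order <- as.integer(raw$order)
  structure(raw, class = "channel_transform")
}
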