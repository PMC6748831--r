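#' Rectangular analysis mask
#'
#' Regions containing vesicle fields are masked before pair cross-correlation
#' so that the complete-spatial-randomness reference is drawn from the same
#' support as the data.
#'
#' @param xmin,xmax,ymin,ymax Mask bounds in nm.
#' @return A mask object usable by [cross_correlation()] and [image_pcc()].
#' @export
mask_rect <- function(xmin, xmax, ymin, ymax) {
  if (xmax <= xmin || ymax <= ymin) abort("mask bounds must be increasing")
  structure(list(type = "rect", xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax),
            class = "coloc_mask")
}

#' Polygonal analysis mask
#'
#' @param x,y Polygon vertex coordinates in nm (closed implicitly).
#' @return A mask object.
#' @export
mask_polygon <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) {
    abort("a polygon mask needs at least 3 matching x/y vertices")
  }
  structure(list(type = "polygon", poly = cbind(x = x, y = y),
                 xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y)),
            class = "coloc_mask")
}

mask_from_points <- function(x, y, pad = 0) {
  mask_rect(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
}

mask_area <- function(mask) {
  if (mask$type == "rect") {
    (mask$xmax - mask$xmin) * (mask$ymax - mask$ymin)
  } else {
    p <- mask$poly
    i <- seq_len(nrow(p)); j <- c(i[-1L], 1L)
    abs(sum(p[i, 1L] * p[j, 2L] - p[j, 1L] * p[i, 2L])) / 2
  }
}

mask_contains <- function(mask, x, y) {
  inb <- x >= mask$xmin & x <= mask$xmax & y >= mask$ymin & y <= mask$ymax
  if (mask$type == "polygon") inb & point_in_polygon(x, y, mask$poly) else inb
}

# Uniform draw of n points inside the mask (rejection sampling for polygons).
mask_runif <- function(mask, n) {
  if (mask$type == "rect") {
    return(tibble(x = runif(n, mask$xmin, mask$xmax),
                  y = runif(n, mask$ymin, mask$ymax)))
  }
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- 2L * (n - length(xs)) + 16L
    cx <- runif(m, mask$xmin, mask$xmax)
    cy <- runif(m, mask$ymin, mask$ymax)
    keep <- point_in_polygon(cx, cy, mask$poly)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  tibble(x = xs[seq_len(n)], y = ys[seq_len(n)])
}
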