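#' Coordinate-based colocalization (CBC)
#'
#' For each localization in channel A, neighbor counts of A and B are
#' accumulated on radii `r_step, 2 r_step, ..., r_max`, converted to
#' area-normalized density distributions
#' `D(r) = (N(r) / r^2) * (r_max^2 / N(r_max))`, rank-correlated (Spearman,
#' average ranks on ties), and the correlation weighted by
#' `exp(-d_nn / r_max)` with `d_nn` the distance to the nearest B neighbor.
#' Values run from -1 (segregated) through 0 (uncorrelated) to +1 (perfectly
#' colocalized). The evaluated point itself is excluded from the A counts,
#' and an exactly coincident B partner (zero distance, e.g. a duplicated
#' channel) is excluded from the B counts so that identical channels score
#' exactly +1. Points with no A neighbor within `r_max` are excluded and
#' counted; points whose density profile is constant in both channels score
#' +1 if the profiles are identical and 0 otherwise.
#'
#' @param a,b Tibbles/data frames with `x_nm`, `y_nm` (same coordinate
#'   frame); the statistic is evaluated per point of `a`.
#' @param r_max Search radius in nm (default 50).
#' @param r_step Radial step in nm (default `r_max / 5`).
#' @param weighting `"nnd"` (exponential nearest-neighbor-distance weight,
#'   default) or `"none"`.
#' @return A tibble of class `cbc_result` with one row per evaluated A
#'   localization (`value`, `nnd_nm`), a `histogram` attribute (0.1-wide bins
#'   over `[-1, 1]`), and `n_excluded`.
#' @export
cbc <- function(a, b, r_max = 50, r_step = r_max / 5,
                weighting = c("nnd", "none")) {
  weighting <- match.arg(weighting)
  assert_cols(a, c("x_nm", "y_nm"), "a"); assert_cols(b, c("x_nm", "y_nm"), "b")
  if (!nrow(a) || !nrow(b)) abort("both point sets must be non-empty")
  radii <- seq(r_step, r_max, by = r_step)
  if (length(radii) < 2) abort("need at least 2 radial steps")
  n <- nrow(a)
  value <- rep(NA_real_, n); nnd_nm <- rep(NA_real_, n)
  chunk <- 1000L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d_aa <- sqrt(pdist2(a$x_nm[idx], a$y_nm[idx], a$x_nm, a$y_nm))
    d_ab <- sqrt(pdist2(a$x_nm[idx], a$y_nm[idx], b$x_nm, b$y_nm))
    # neighbor counts per radius; self excluded from the A counts
    na_r <- vapply(radii, function(r) rowSums(d_aa <= r) - 1, numeric(length(idx)))
    nb_r <- vapply(radii, function(r) rowSums(d_ab <= r & d_ab > 0),
                   numeric(length(idx)))
    if (length(idx) == 1L) { na_r <- rbind(na_r); nb_r <- rbind(nb_r) }
    nnd_nm[idx] <- apply(d_ab, 1L, min)
    for (k in seq_along(idx)) {
      na_max <- na_r[k, length(radii)]
      if (na_max == 0) next  # isolated in A: undefined, excluded
      da <- na_r[k, ] / radii^2 * r_max^2 / na_max
      nb_max <- nb_r[k, length(radii)]
      db <- if (nb_max > 0) nb_r[k, ] / radii^2 * r_max^2 / nb_max else
        rep(0, length(radii))
      s <- spearman_rho(da, db)
      w <- if (weighting == "nnd") exp(-nnd_nm[idx[k]] / r_max) else 1
      value[idx[k]] <- min(1, max(-1, s * w))
    }
  }
  keep <- !is.na(value)
  out <- tibble(index = which(keep), value = value[keep],
                nnd_nm = nnd_nm[keep])
  breaks <- seq(-1, 1, by = 0.1)
  counts <- as.integer(table(cut(out$value, breaks, include.lowest = TRUE)))
  attr(out, "histogram") <- tibble(bin_mid = breaks[-1] - 0.05,
                                   count = counts)
  attr(out, "n_excluded") <- n - nrow(out)
  attr(out, "params") <- list(r_max = r_max, r_step = r_step,
                              weighting = weighting)
  class(out) <- c("cbc_result", class(out))
  out
}

# Spearman rank correlation with average ranks; the degenerate constant-
# profile cases carry the convention documented in cbc().
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (all(rx == ry)) return(1)
  sx <- sd(rx); sy <- sd(ry)
  if (sx == 0 || sy == 0) {
    return(if (sx == 0 && sy == 0 && all(x == y)) 1 else 0)
  }
  mean((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy) * length(x) /
    (length(x) - 1)
}

#' Nearest-neighbor distances between two channels
#'
#' Exact Euclidean distance from each localization of channel A to its
#' closest localization in channel B, optionally summarized as the median per
#' cell.
#'
#' @param a,b Tibbles with `x_nm`, `y_nm`; `b` must be non-empty.
#' @param cell Optional per-row cell labels for `a`.
#' @return A tibble of class `nnd_result` (`dist_nm`, optional `cell`); the
#'   per-cell medians are available via [nnd_per_cell()].
#' @export
nnd <- function(a, b, cell = NULL) {
  assert_cols(a, c("x_nm", "y_nm"), "a"); assert_cols(b, c("x_nm", "y_nm"), "b")
  if (!nrow(b)) abort("channel B is empty; nearest-neighbor distance undefined")
  if (!nrow(a)) abort("channel A is empty")
  out <- tibble(dist_nm = nn_dist(a$x_nm, a$y_nm, b$x_nm, b$y_nm))
  if (!is.null(cell)) out$cell <- rep(cell, length.out = nrow(out))
  class(out) <- c("nnd_result", class(out))
  out
}

#' @rdname nnd
#' @param result An `nnd_result` with a `cell` column.
#' @export
nnd_per_cell <- function(result) {
  assert_cols(result, "cell", "result")
  summarise(group_by(result, .data$cell),
            median_nnd_nm = median(.data$dist_nm), n = dplyr::n(),
            .groups = "drop")
}

#' Angular-averaged pair cross-correlation of two point patterns
#'
#' Tabulates all A-B pair distances into radial bins up to `r_max` and
#' normalizes by the mean histogram of `n_random` seeded draws of the same
#' point counts distributed completely at random inside the mask, which
#' supplies the edge correction for arbitrary masks. `C(r) = 1` for randomly
#' co-distributed molecules; `C(r) > 1` indicates co-clustering at that
#' distance. The per-bin uncertainty is the standard deviation of the CSR
#' draws on the normalized scale.
#'
#' @param a,b Point tibbles (`x_nm`, `y_nm`) inside the mask.
#' @param mask A [mask_rect()]/[mask_polygon()]; defaults to the joint
#'   bounding box.
#' @param r_max Maximum radial distance in nm (default 1000).
#' @param bin_width Radial bin width in nm (default 10).
#' @param n_random Number of CSR reference draws (>= 10).
#' @param seed Seed for the reference draws.
#' @return A tibble of class `cross_correlogram` (`r_nm` bin centers, `C`,
#'   `uncertainty`) with normalization metadata attributes.
#' @export
cross_correlation <- function(a, b, mask = NULL, r_max = 1000,
                              bin_width = 10, n_random = 20, seed = 1) {
  assert_cols(a, c("x_nm", "y_nm"), "a"); assert_cols(b, c("x_nm", "y_nm"), "b")
  if (!nrow(a) || !nrow(b)) abort("both point sets must be non-empty")
  if (n_random < 10) abort("`n_random` must be at least 10")
  mask <- mask %||% mask_from_points(c(a$x_nm, b$x_nm), c(a$y_nm, b$y_nm))
  if (!all(mask_contains(mask, a$x_nm, a$y_nm)) ||
      !all(mask_contains(mask, b$x_nm, b$y_nm))) {
    abort("all points must lie inside the mask")
  }
  breaks <- seq(0, r_max, by = bin_width)
  h_obs <- pair_hist(a$x_nm, a$y_nm, b$x_nm, b$y_nm, breaks)
  h_rand <- with_seed(seed, {
    vapply(seq_len(n_random), function(k) {
      ra <- mask_runif(mask, nrow(a)); rb <- mask_runif(mask, nrow(b))
      pair_hist(ra$x, ra$y, rb$x, rb$y, breaks)
    }, numeric(length(breaks) - 1L))
  })
  h_mean <- rowMeans(h_rand)
  h_sd <- apply(h_rand, 1L, sd)
  C <- ifelse(h_mean > 0, h_obs / h_mean, NA_real_)
  uncertainty <- ifelse(h_mean > 0, h_sd / h_mean, NA_real_)
  out <- tibble(r_nm = breaks[-1] - bin_width / 2, C = C,
                uncertainty = uncertainty)
  attr(out, "params") <- list(r_max = r_max, bin_width = bin_width,
                              n_random = n_random, seed = seed,
                              mask_area = mask_area(mask),
                              n_a = nrow(a), n_b = nrow(b))
  class(out) <- c("cross_correlogram", class(out))
  out
}

pair_hist <- function(ax, ay, bx, by, breaks) {
  n <- length(ax)
  acc <- numeric(length(breaks) - 1L)
  chunk <- max(1L, floor(4e6 / length(bx)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d <- sqrt(pdist2(ax[idx], ay[idx], bx, by))
    d <- d[d > 0 & d <= breaks[length(breaks)]]
    if (length(d)) {
      acc <- acc + tabulate(findInterval(d, breaks, left.open = TRUE),
                            nbins = length(breaks) - 1L)
    }
  }
  acc
}

#' Peak distance of a cross-correlogram
#'
#' Bins whose CSR normalization is poorly determined (relative uncertainty
#' above `max_uncertainty`, typically the shortest distances where the
#' reference histogram holds only a handful of pairs) are excluded from the
#' peak search; if every bin is that noisy the search falls back to all
#' finite bins.
#'
#' @param correlogram A `cross_correlogram`.
#' @param max_uncertainty Maximum per-bin relative uncertainty admitted to
#'   the peak search (default 0.25).
#' @return The bin-center distance (nm) at which C(r) is maximal.
#' @export
xcorr_peak <- function(correlogram, max_uncertainty = 0.25) {
  ok <- is.finite(correlogram$C) & is.finite(correlogram$uncertainty) &
    correlogram$uncertainty <= max_uncertainty
  if (!any(ok)) ok <- is.finite(correlogram$C)
  correlogram$r_nm[ok][which.max(correlogram$C[ok])]
}

#' Image-level Pearson correlation
#'
#' Standard Pearson coefficient between two rendered images over masked
#' pixels. Errors on constant images (the coefficient is undefined).
#'
#' @param img1,img2 `rendered_image` objects or plain matrices on the same
#'   grid.
#' @param mask Optional logical matrix of pixels to include.
#' @return A list of class `pcc_result`: `pcc`, `n_pixels`.
#' @export
image_pcc <- function(img1, img2, mask = NULL) {
  m1 <- if (inherits(img1, "rendered_image")) img1$intensity else img1
  m2 <- if (inherits(img2, "rendered_image")) img2$intensity else img2
  if (!all(dim(m1) == dim(m2))) abort("images must share the same grid")
  sel <- if (is.null(mask)) rep(TRUE, length(m1)) else as.logical(mask)
  v1 <- as.numeric(m1)[sel]; v2 <- as.numeric(m2)[sel]
  if (!length(v1)) abort("mask selects no pixels")
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Pearson coefficient undefined for a constant image")
  }
  structure(list(pcc = cor(v1, v2), n_pixels = length(v1)),
            class = "pcc_result")
}
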