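# Fixture generators and independent brute-force oracles used across tests.

# n points uniform in a disk
points_in_disk <- function(n, cx = 0, cy = 0, r = 25) {
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  tibble::tibble(x_nm = cx + rr * cos(th), y_nm = cy + rr * sin(th))
}

# n points uniform in an annulus
points_in_annulus <- function(n, cx = 0, cy = 0, r0 = 30, r1 = 50) {
  th <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n, r0^2, r1^2))
  tibble::tibble(x_nm = cx + rr * cos(th), y_nm = cy + rr * sin(th))
}

csr_points <- function(n, xmax = 2000, ymax = xmax) {
  tibble::tibble(x_nm = runif(n, 0, xmax), y_nm = runif(n, 0, ymax))
}

# O(n^2) nearest-neighbor oracle
nnd_brute <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((b$x_nm - a$x_nm[i])^2 + (b$y_nm - a$y_nm[i])^2))
  }, numeric(1))
}

# Slow per-point CBC oracle: explicit loops, stats::cor for the Spearman
# step, same neighbor conventions as the documented statistic.
cbc_brute <- function(a, b, r_max = 50, r_step = r_max / 5) {
  radii <- seq(r_step, r_max, by = r_step)
  out <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    d_aa <- sqrt((a$x_nm - a$x_nm[i])^2 + (a$y_nm - a$y_nm[i])^2)[-i]
    d_ab <- sqrt((b$x_nm - a$x_nm[i])^2 + (b$y_nm - a$y_nm[i])^2)
    na_r <- vapply(radii, function(r) sum(d_aa <= r), numeric(1))
    if (na_r[length(radii)] == 0) next
    nb_r <- vapply(radii, function(r) sum(d_ab <= r & d_ab > 0), numeric(1))
    da <- na_r / radii^2 * r_max^2 / na_r[length(radii)]
    db <- if (nb_r[length(radii)] > 0) {
      nb_r / radii^2 * r_max^2 / nb_r[length(radii)]
    } else rep(0, length(radii))
    s <- suppressWarnings(cor(da, db, method = "spearman"))
    if (is.na(s)) s <- if (sd(da) == 0 && sd(db) == 0 && all(da == db)) 1 else 0
    out[i] <- s * exp(-min(d_ab) / r_max)
  }
  out
}

# Noiseless pixel-integrated Gaussian frame for fitter tests
gaussian_frame <- function(nx, ny, cx_px, cy_px, photons, sigma_px, bg = 0) {
  px <- diff(pnorm(0:nx, cx_px, sigma_px))
  py <- diff(pnorm(0:ny, cy_px, sigma_px))
  photons * (py %o% px) + bg
}

# Small localization table builder
loc_table <- function(frame, x_nm, y_nm, photons = 3000, sigma_nm = 150,
                      precision_nm = 10, channel = "640",
                      pixel_size_nm = 107) {
  tb <- tibble::tibble(channel = channel, frame = frame, x_nm = x_nm,
                       y_nm = y_nm, photons = photons, sigma_nm = sigma_nm,
                       precision_nm = precision_nm)
  attr(tb, "pixel_size_nm") <- pixel_size_nm
  tb
}

# Random confidence-scored graph on n nodes (guaranteed non-empty)
random_edges <- function(n, p = 0.3) {
  pairs <- t(combn(sprintf("g%02d", seq_len(n)), 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  tibble::tibble(a = pairs[keep, 1], b = pairs[keep, 2],
                 score = runif(sum(keep), 0.4, 0.999))
}
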