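#' Estimate stage drift from frame-subset image correlation
#'
#' Splits the acquisition into consecutive subsets of `subset_frames` frames,
#' reconstructs a 2-D histogram image from each subset, and estimates the
#' displacement of every subset relative to the first (the reference time
#' segment) by FFT cross-correlation with three-point parabolic sub-pixel
#' peak interpolation per axis. Displacements are interpolated
#' piecewise-linearly between subset-center frames, with constant
#' extrapolation at the ends.
#'
#' @param table Localization tibble (single channel or pooled) with `frame`,
#'   `x_nm`, `y_nm`.
#' @param subset_frames Frames per subset (default 500).
#' @param render_pixel_nm Pixel size of the correlation images; defaults to
#'   one tenth of the table's camera pixel, fine enough for stable sub-pixel
#'   peak interpolation.
#' @param min_locs Minimum localizations per subset; sparser subsets are
#'   flagged and interpolated over.
#' @return A `drift_trajectory`: tibble (knot_frame, dx_nm, dy_nm, flagged)
#'   with attributes `frame_range` and `interpolation`.
#' @export
estimate_drift <- function(table, subset_frames = 500,
                           render_pixel_nm = NULL, min_locs = 20) {
  assert_cols(table, c("frame", "x_nm", "y_nm"), "table")
  render_pixel_nm <- render_pixel_nm %||%
    ((attr(table, "pixel_size_nm") %||% 107) / 10)
  f0 <- min(table$frame); f1 <- max(table$frame)
  n_subsets <- floor((f1 - f0 + 1) / subset_frames)
  if (n_subsets < 2) abort("table must span at least 2 frame subsets")
  sub <- pmin(floor((table$frame - f0) / subset_frames) + 1, n_subsets)
  ext <- c(min(table$x_nm), max(table$x_nm) + render_pixel_nm,
           min(table$y_nm), max(table$y_nm) + render_pixel_nm)
  nx <- ceiling((ext[2] - ext[1]) / render_pixel_nm)
  ny <- ceiling((ext[4] - ext[3]) / render_pixel_nm)
  imgs <- lapply(seq_len(n_subsets), function(k) {
    idx <- sub == k
    if (sum(idx) < min_locs) return(NULL)
    bin_image(table$x_nm[idx], table$y_nm[idx], render_pixel_nm, ext, nx, ny)
  })
  if (is.null(imgs[[1]])) abort("reference subset has too few localizations")
  ref_fft <- fft(imgs[[1]])
  dx <- dy <- rep(NA_real_, n_subsets)
  dx[1] <- dy[1] <- 0
  for (k in seq_len(n_subsets)[-1]) {
    if (is.null(imgs[[k]])) next
    sh <- fft_shift_peak(ref_fft, imgs[[k]])
    dx[k] <- sh[1] * render_pixel_nm
    dy[k] <- sh[2] * render_pixel_nm
  }
  knot_frame <- f0 + (seq_len(n_subsets) - 0.5) * subset_frames
  flagged <- !is.finite(dx)
  if (any(flagged)) {
    ok <- which(!flagged)
    dx[flagged] <- approx(knot_frame[ok], dx[ok], knot_frame[flagged],
                          rule = 2)$y
    dy[flagged] <- approx(knot_frame[ok], dy[ok], knot_frame[flagged],
                          rule = 2)$y
  }
  out <- tibble(knot_frame = knot_frame, dx_nm = dx, dy_nm = dy,
                flagged = flagged)
  attr(out, "frame_range") <- c(f0, f1)
  attr(out, "interpolation") <- "linear"
  class(out) <- c("drift_trajectory", class(out))
  out
}

bin_image <- function(x, y, pixel, ext, nx, ny) {
  cx <- pmin(pmax(floor((x - ext[1]) / pixel) + 1L, 1L), nx)
  cy <- pmin(pmax(floor((y - ext[3]) / pixel) + 1L, 1L), ny)
  counts <- tabulate((cx - 1L) * ny + cy, nbins = nx * ny)
  matrix(counts, nrow = ny, ncol = nx)
}

# Displacement of img relative to the reference (whose fft is ref_fft), in
# pixels, via circular cross-correlation with parabolic refinement.
fft_shift_peak <- function(ref_fft, img) {
  cc <- Re(fft(ref_fft * Conj(fft(img)), inverse = TRUE))
  ny <- nrow(cc); nx <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap_r <- function(i) ((i - 1) %% ny) + 1
  wrap_c <- function(i) ((i - 1) %% nx) + 1
  para <- function(m, c0, p) {
    # parabolic refinement on the log scale (exact for a Gaussian peak) when
    # all three samples are positive, else on the raw values
    if (m > 0 && c0 > 0 && p > 0) {
      m <- log(m); c0 <- log(c0); p <- log(p)
    }
    denom <- m - 2 * c0 + p
    if (abs(denom) < 1e-12) 0 else 0.5 * (m - p) / denom
  }
  dr <- para(cc[wrap_r(pk[1] - 1), pk[2]], cc[pk[1], pk[2]],
             cc[wrap_r(pk[1] + 1), pk[2]])
  dc <- para(cc[pk[1], wrap_c(pk[2] - 1)], cc[pk[1], pk[2]],
             cc[pk[1], wrap_c(pk[2] + 1)])
  ix <- pk[2] - 1 + dc; iy <- pk[1] - 1 + dr
  if (ix > nx / 2) ix <- ix - nx
  if (iy > ny / 2) iy <- iy - ny
  # correlation conj(img) against ref: peak at ref - img = -shift of img
  c(-ix, -iy)
}

#' Displacement of a drift trajectory at given frames
#'
#' @param trajectory A `drift_trajectory`.
#' @param frames Frame indices.
#' @return Matrix with columns dx, dy (nm).
#' @export
drift_displacement <- function(trajectory, frames) {
  cbind(dx = approx(trajectory$knot_frame, trajectory$dx_nm, frames,
                    rule = 2)$y,
        dy = approx(trajectory$knot_frame, trajectory$dy_nm, frames,
                    rule = 2)$y)
}

#' Subtract estimated drift from a localization table
#'
#' Shifts every localization by minus the trajectory displacement at its
#' frame. Not idempotent: applying a non-zero correction twice shifts twice.
#'
#' @param table Localization tibble.
#' @param trajectory A `drift_trajectory` covering the table's frame range.
#' @return The corrected tibble (row count unchanged).
#' @export
apply_drift_correction <- function(table, trajectory) {
  assert_cols(table, c("frame", "x_nm", "y_nm"), "table")
  fr <- attr(trajectory, "frame_range")
  if (!is.null(fr) && (min(table$frame) < fr[1] || max(table$frame) > fr[2])) {
    abort("table frames fall outside the trajectory's frame range")
  }
  d <- drift_displacement(trajectory, table$frame)
  out <- table
  out$x_nm <- table$x_nm - d[, 1]
  out$y_nm <- table$y_nm - d[, 2]
  keep_attrs(out, table)
}

#' Serialize / restore a drift trajectory as structured text (CSV)
#'
#' The knot table is written with its frame range in comment headers so the
#' trajectory round-trips exactly.
#'
#' @param trajectory A `drift_trajectory`.
#' @param path Output file.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   the restored trajectory.
#' @export
write_trajectory <- function(trajectory, path) {
  fr <- attr(trajectory, "frame_range")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_range %g %g", fr[1], fr[2]), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1L)
  fr <- as.numeric(strsplit(sub("^# frame_range ", "", header), " ")[[1]])
  out <- as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(out, "frame_range") <- fr
  attr(out, "interpolation") <- "linear"
  class(out) <- c("drift_trajectory", class(out))
  out
}
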