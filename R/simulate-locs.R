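#' Fluorophore blinking model
#'
#' Each labeled molecule produces a number of blink events spread over the
#' acquisition; each event is a run of consecutive frames. Run lengths are
#' geometric (so `mean_on_frames = 1` gives exactly one frame per blink) and
#' photon counts per emitted localization are log-normal with the stated mean,
#' which exercises both the photon threshold filter and the
#' consecutive-frame merging rule downstream.
#'
#' @param mean_blinks Mean blink events per labeled fluorophore (>= 1; the
#'   count is 1 + Poisson(mean_blinks - 1), so a mean of 1 is exact).
#' @param mean_on_frames Mean consecutive-frame run length per blink (>= 1).
#' @param photon_mean Mean photons per emitted localization.
#' @param photon_sdlog Log-sd of the photon distribution (0 = deterministic).
#' @param labeling_efficiency Fraction of molecules carrying a label, in
#'   `[0, 1]`.
#' @return A validated blink-model list.
#' @export
blink_model <- function(mean_blinks = 4, mean_on_frames = 2,
                        photon_mean = 4000, photon_sdlog = 0.3,
                        labeling_efficiency = 0.8) {
  assert_number(mean_blinks, "mean_blinks", lower = 1)
  assert_number(mean_on_frames, "mean_on_frames", lower = 1)
  assert_number(photon_mean, "photon_mean", lower = 0, strict = TRUE)
  assert_number(photon_sdlog, "photon_sdlog", lower = 0)
  assert_number(labeling_efficiency, "labeling_efficiency", 0, 1)
  list(mean_blinks = mean_blinks, mean_on_frames = mean_on_frames,
       photon_mean = photon_mean, photon_sdlog = photon_sdlog,
       labeling_efficiency = labeling_efficiency)
}

#' Drift models
#'
#' `drift_none()` disables stage drift; `drift_linear()` injects a constant
#' velocity in nm/frame; `drift_knots()` takes a piecewise-linear trajectory.
#'
#' @param rate_nm_per_frame Length-2 c(dx, dy) velocity in nm/frame.
#' @param frames,dx_nm,dy_nm Knot frames (strictly increasing) and
#'   displacements for `drift_knots`.
#' @return A drift specification.
#' @export
drift_none <- function() {
  structure(list(type = "none"), class = "drift_spec")
}

#' @rdname drift_none
#' @export
drift_linear <- function(rate_nm_per_frame = c(0.05, 0.05)) {
  stopifnot(length(rate_nm_per_frame) == 2)
  structure(list(type = "linear", rate = rate_nm_per_frame),
            class = "drift_spec")
}

#' @rdname drift_none
#' @export
drift_knots <- function(frames, dx_nm, dy_nm) {
  stopifnot(length(frames) == length(dx_nm),
            length(frames) == length(dy_nm),
            all(diff(frames) > 0))
  structure(list(type = "knots", frames = frames, dx = dx_nm, dy = dy_nm),
            class = "drift_spec")
}

# Displacement (nm) at the given frames; matrix with columns dx, dy.
drift_at <- function(drift, frames) {
  switch(drift$type,
    none = cbind(dx = numeric(length(frames)), dy = numeric(length(frames))),
    linear = cbind(dx = (frames - 1) * drift$rate[1],
                   dy = (frames - 1) * drift$rate[2]),
    knots = cbind(
      dx = approx(drift$frames, drift$dx, frames, rule = 2)$y,
      dy = approx(drift$frames, drift$dy, frames, rule = 2)$y),
    abort("unknown drift type"))
}

#' Inter-channel warp models
#'
#' A smooth displacement field applied to the non-reference channel before
#' localization noise, emulating the chromatic/optical mismatch that fiducial
#' registration must undo. `warp_affine()` rotates by `rot_deg` and scales
#' about `center_nm`, then shifts by `c(dx_nm, dy_nm)`.
#'
#' @param dx_nm,dy_nm Translation in nm.
#' @param rot_deg Rotation in degrees.
#' @param scale Isotropic scale factor.
#' @param center_nm Length-2 rotation/scale center in nm.
#' @return A warp specification.
#' @export
warp_none <- function() structure(list(type = "none"), class = "warp_spec")

#' @rdname warp_none
#' @export
warp_affine <- function(dx_nm = 0, dy_nm = 0, rot_deg = 0, scale = 1,
                        center_nm = c(0, 0)) {
  structure(list(type = "affine", dx = dx_nm, dy = dy_nm,
                 rot = rot_deg * pi / 180, scale = scale, center = center_nm),
            class = "warp_spec")
}

warp_xy <- function(warp, x, y) {
  if (warp$type == "none") return(list(x = x, y = y))
  cs <- cos(warp$rot); sn <- sin(warp$rot)
  xr <- x - warp$center[1]; yr <- y - warp$center[2]
  list(x = warp$center[1] + warp$scale * (cs * xr - sn * yr) + warp$dx,
       y = warp$center[2] + warp$scale * (sn * xr + cs * yr) + warp$dy)
}

#' Acquisition configuration
#'
#' @param pixel_size_nm Camera pixel size in nm (107 nm default, a 150x
#'   EMCCD geometry).
#' @param n_frames Number of acquisition frames (default 5000).
#' @param exposure_ms Effective exposure per frame in ms.
#' @param precision_nm Localization error sigma in nm: a single value or a
#'   named vector per channel ("488", "561", "640").
#' @param psf_sigma_nm PSF Gaussian sigma in nm (for raw-frame simulation and
#'   the `sigma_nm` column of localization tables).
#' @param background_photons Poisson background per pixel per frame (raw-frame
#'   simulation only).
#' @param drift A drift specification ([drift_none()], [drift_linear()],
#'   [drift_knots()]).
#' @param warp A warp specification applied to `warp_channel`.
#' @param warp_channel Channel the warp applies to (the 488 nm channel is
#'   mapped onto the 640 nm reference; 561 passes through unregistered).
#' @param fiducial_photons Photons per fiducial localization per frame.
#' @param fiducial_precision_nm Localization error of fiducial fits (nm).
#' @return A validated acquisition configuration list.
#' @export
acquisition_config <- function(pixel_size_nm = 107, n_frames = 5000,
                               exposure_ms = 10, precision_nm = 10,
                               psf_sigma_nm = 150, background_photons = 2,
                               drift = drift_none(), warp = warp_none(),
                               warp_channel = "488",
                               fiducial_photons = 2e4,
                               fiducial_precision_nm = 2) {
  assert_number(pixel_size_nm, "pixel_size_nm", lower = 0, strict = TRUE)
  assert_number(n_frames, "n_frames", lower = 1)
  stopifnot(all(precision_nm >= 0), psf_sigma_nm > 0, background_photons >= 0)
  list(pixel_size_nm = pixel_size_nm, n_frames = as.integer(n_frames),
       exposure_ms = exposure_ms, precision_nm = precision_nm,
       psf_sigma_nm = psf_sigma_nm, background_photons = background_photons,
       drift = drift, warp = warp, warp_channel = warp_channel,
       fiducial_photons = fiducial_photons,
       fiducial_precision_nm = fiducial_precision_nm)
}

channel_precision <- function(acq, channel) {
  p <- acq$precision_nm
  if (is.null(names(p))) rep(p[1], length(channel)) else {
    out <- unname(p[channel])
    out[is.na(out)] <- p[1]
    out
  }
}

# One row per blink event for each labeled molecule: (molecule index, start
# frame, run length).
blink_schedule <- function(n_molecules, blink, n_frames) {
  labeled <- which(runif(n_molecules) <= blink$labeling_efficiency)
  if (!length(labeled)) {
    return(tibble(molecule = integer(), frame = integer()))
  }
  n_blinks <- 1L + rpois(length(labeled), blink$mean_blinks - 1)
  mol <- rep(labeled, n_blinks)
  n_events <- length(mol)
  start <- sample.int(n_frames, n_events, replace = TRUE)
  runs <- 1L + rgeom(n_events, 1 / blink$mean_on_frames)
  frame <- unlist(lapply(seq_len(n_events), function(i) {
    seq(start[i], min(start[i] + runs[i] - 1L, n_frames))
  }))
  tibble(molecule = rep(mol, pmin(runs, n_frames - start + 1L)), frame = frame)
}

#' Simulate dSTORM localization tables from a scene
#'
#' Forward model: each emitted localization is the molecule position plus the
#' stage drift at its frame, plus the inter-channel warp (for the warped
#' channel only), plus isotropic Gaussian localization error. Fiducial beads
#' appear in every frame of every channel. Truth columns (`x_true_nm`,
#' `y_true_nm`, `molecule`, `vesicle`) ride along for truth matching and are
#' dropped on CSV export.
#'
#' @param scene An `se_scene` from [generate_scene()].
#' @param blink A [blink_model()].
#' @param acq An [acquisition_config()].
#' @param seed Integer seed (pure function of inputs and seed).
#' @return A list of class `smlm_sim` with tibbles `locs` and `fiducial_locs`,
#'   both sorted by channel then frame, carrying `pixel_size_nm` and
#'   `n_frames` attributes.
#' @export
simulate_localizations <- function(scene, blink = blink_model(),
                                   acq = acquisition_config(), seed = 1) {
  with_seed(seed, {
    mols <- scene$molecules
    sched <- blink_schedule(nrow(mols), blink, acq$n_frames)
    drift <- drift_at(acq$drift, sched$frame)
    ch <- mols$channel[sched$molecule]
    x0 <- mols$x_nm[sched$molecule]
    y0 <- mols$y_nm[sched$molecule]
    x <- x0 + drift[, 1]; y <- y0 + drift[, 2]
    warped <- ch == acq$warp_channel
    if (any(warped) && acq$warp$type != "none") {
      w <- warp_xy(acq$warp, x[warped], y[warped])
      x[warped] <- w$x; y[warped] <- w$y
    }
    prec <- channel_precision(acq, ch)
    n <- nrow(sched)
    photons <- if (blink$photon_sdlog > 0) {
      rlnorm(n, log(blink$photon_mean) - blink$photon_sdlog^2 / 2,
             blink$photon_sdlog)
    } else rep(blink$photon_mean, n)
    locs <- tibble(
      channel = ch, frame = sched$frame,
      x_nm = x + rnorm(n, 0, 1) * prec,
      y_nm = y + rnorm(n, 0, 1) * prec,
      photons = photons, sigma_nm = acq$psf_sigma_nm, precision_nm = prec,
      molecule = sched$molecule,
      vesicle = mols$vesicle[sched$molecule],
      x_true_nm = x0, y_true_nm = y0
    )
    locs <- arrange(locs, .data$channel, .data$frame)

    fid <- scene$fiducials
    channels <- sort(unique(c(mols$channel, "488", "561", "640")))
    nf <- nrow(fid)
    if (nf > 0) {
      grid <- expand.grid(fiducial = fid$fiducial, frame = seq_len(acq$n_frames),
                          channel = channels, stringsAsFactors = FALSE)
      fx <- fid$x_nm[match(grid$fiducial, fid$fiducial)]
      fy <- fid$y_nm[match(grid$fiducial, fid$fiducial)]
      fdrift <- drift_at(acq$drift, grid$frame)
      gx <- fx + fdrift[, 1]; gy <- fy + fdrift[, 2]
      warped <- grid$channel == acq$warp_channel
      if (any(warped) && acq$warp$type != "none") {
        w <- warp_xy(acq$warp, gx[warped], gy[warped])
        gx[warped] <- w$x; gy[warped] <- w$y
      }
      m <- nrow(grid)
      fiducial_locs <- tibble(
        channel = grid$channel, frame = grid$frame,
        x_nm = gx + rnorm(m, 0, acq$fiducial_precision_nm),
        y_nm = gy + rnorm(m, 0, acq$fiducial_precision_nm),
        photons = acq$fiducial_photons, sigma_nm = acq$psf_sigma_nm,
        precision_nm = acq$fiducial_precision_nm,
        fiducial = grid$fiducial, x_true_nm = fx, y_true_nm = fy
      )
      fiducial_locs <- arrange(fiducial_locs, .data$channel, .data$frame)
    } else {
      fiducial_locs <- tibble(channel = character(), frame = integer(),
                              x_nm = numeric(), y_nm = numeric(),
                              photons = numeric(), sigma_nm = numeric(),
                              precision_nm = numeric(), fiducial = integer(),
                              x_true_nm = numeric(), y_true_nm = numeric())
    }
    attr(locs, "pixel_size_nm") <- acq$pixel_size_nm
    attr(locs, "n_frames") <- acq$n_frames
    attr(fiducial_locs, "pixel_size_nm") <- acq$pixel_size_nm
    attr(fiducial_locs, "n_frames") <- acq$n_frames
    structure(list(locs = locs, fiducial_locs = fiducial_locs),
              class = "smlm_sim")
  })
}
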