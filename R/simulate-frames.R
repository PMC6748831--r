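#' Simulate a raw single-molecule image stack
#'
#' Renders each active emitter as a pixel-integrated 2-D Gaussian PSF with its
#' drawn photon count, on a Poisson background, for a small field of view.
#' Intended to exercise the peak-detection and Gaussian-fitting stage; for
#' full-field work use [simulate_localizations()] directly.
#'
#' @param scene An `se_scene` whose field fits the pixel budget, or `NULL` to
#'   use `emitters` directly.
#' @param blink A [blink_model()].
#' @param acq An [acquisition_config()]; `psf_sigma_nm`, `pixel_size_nm` and
#'   `background_photons` control the rendering.
#' @param seed Integer seed.
#' @param emitters Optional tibble (x_nm, y_nm) of molecule positions
#'   overriding the scene molecules.
#' @param n_frames Number of frames (defaults to `acq$n_frames`).
#' @param max_pixels Size guard: fields larger than this per side are refused.
#' @return A list of class `frame_sim`: `frames` (array y-by-x-by-frame),
#'   `truth` (tibble frame, molecule, x_nm, y_nm, photons of active
#'   emitters), `pixel_size_nm`, `field_px`.
#' @export
simulate_frames <- function(scene = NULL, blink = blink_model(),
                            acq = acquisition_config(), seed = 1,
                            emitters = NULL, n_frames = NULL,
                            max_pixels = 64L) {
  if (is.null(emitters)) {
    if (is.null(scene)) abort("supply a scene or an emitters table")
    emitters <- scene$molecules[, c("x_nm", "y_nm")]
    field <- scene$field_size_nm
  } else {
    assert_cols(emitters, c("x_nm", "y_nm"), "emitters")
    field <- c(max(emitters$x_nm), max(emitters$y_nm)) + 8 * acq$psf_sigma_nm
  }
  n_frames <- n_frames %||% acq$n_frames
  npx <- ceiling(field / acq$pixel_size_nm)
  if (any(npx > max_pixels)) {
    abort(sprintf("field of %d x %d px exceeds the %d px budget; use a smaller scene",
                  npx[1], npx[2], max_pixels))
  }
  nx <- npx[1]; ny <- npx[2]
  with_seed(seed, {
    sched <- blink_schedule(nrow(emitters), blink, n_frames)
    nloc <- nrow(sched)
    photons <- if (blink$photon_sdlog > 0) {
      rlnorm(nloc, log(blink$photon_mean) - blink$photon_sdlog^2 / 2,
             blink$photon_sdlog)
    } else rep(blink$photon_mean, nloc)
    truth <- tibble(frame = sched$frame, molecule = sched$molecule,
                    x_nm = emitters$x_nm[sched$molecule],
                    y_nm = emitters$y_nm[sched$molecule],
                    photons = photons)
    truth <- arrange(truth, .data$frame)
    sig_px <- acq$psf_sigma_nm / acq$pixel_size_nm
    frames <- array(0, dim = c(ny, nx, n_frames))
    edges_x <- seq(0, nx); edges_y <- seq(0, ny)
    for (i in seq_len(nrow(truth))) {
      cx <- truth$x_nm[i] / acq$pixel_size_nm
      cy <- truth$y_nm[i] / acq$pixel_size_nm
      px <- diff(stats::pnorm(edges_x, cx, sig_px))
      py <- diff(stats::pnorm(edges_y, cy, sig_px))
      frames[, , truth$frame[i]] <- frames[, , truth$frame[i]] +
        truth$photons[i] * (py %o% px)
    }
    if (acq$background_photons > 0) {
      frames <- frames + array(rpois(length(frames), acq$background_photons),
                               dim = dim(frames))
    }
    structure(list(frames = frames, truth = truth,
                   pixel_size_nm = acq$pixel_size_nm, field_px = c(nx, ny)),
              class = "frame_sim")
  })
}

#' Write an image stack as multi-page TIFF
#'
#' @param frames A 3-D array (y, x, frame) or a `frame_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  if (inherits(frames, "frame_sim")) frames <- frames$frames
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to write TIFF stacks")
  }
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(k) frames[, , k] / max(frames[, , k], 1))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Read a multi-page TIFF stack into an array
#'
#' @param path TIFF file path.
#' @return A 3-D array (y, x, frame).
#' @export
read_frames_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the 'tiff' package is required to read TIFF stacks")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.list(pages)) {
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  } else array(pages, dim = c(dim(pages), 1L))
}
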