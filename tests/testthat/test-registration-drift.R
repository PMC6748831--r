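# Repeating-structure localization table with injected drift: m molecules at
# fixed positions, k re-blinks each, uniform over frames.
drifting_table <- function(seed, drift, n_frames = 5000, n_mol = 2000,
                           k = 10, field = 5000, sigma = 5) {
  set.seed(seed)
  mx <- runif(n_mol, 0, field); my <- runif(n_mol, 0, field)
  frame <- sample.int(n_frames, n_mol * k, replace = TRUE)
  mol <- rep(seq_len(n_mol), each = k)
  d <- ectostorm:::drift_at(drift, frame)
  tb <- tibble::tibble(frame = frame,
                       x_nm = mx[mol] + d[, 1] + rnorm(n_mol * k, 0, sigma),
                       y_nm = my[mol] + d[, 2] + rnorm(n_mol * k, 0, sigma),
                       x_true_nm = mx[mol], y_true_nm = my[mol])
  attr(tb, "pixel_size_nm") <- 107
  tb
}

trajectory_rmse <- function(traj, drift, n_frames, ref_frames = 1:500) {
  frames <- seq_len(n_frames)
  truth <- ectostorm:::drift_at(drift, frames)
  ref <- colMeans(ectostorm:::drift_at(drift, ref_frames))
  est <- drift_displacement(traj, frames)
  sqrt(mean((est[, 1] - (truth[, 1] - ref[1]))^2 +
            (est[, 2] - (truth[, 2] - ref[2]))^2))
}

test_that("zero injected drift is recovered as (almost) no drift", {
  tb <- drifting_table(101, drift_none(), n_frames = 2000, n_mol = 1500,
                       k = 8)
  traj <- estimate_drift(tb, subset_frames = 500)
  expect_true(all(abs(traj$dx_nm) < 2))
  expect_true(all(abs(traj$dy_nm) < 2))
  expect_equal(traj$dx_nm[1], 0)
})

test_that("linear drift of 0.05 nm/frame over 5000 frames is recovered", {
  drift <- drift_linear(c(0.05, 0.05))
  tb <- drifting_table(102, drift)
  traj <- estimate_drift(tb, subset_frames = 500)
  expect_lt(trajectory_rmse(traj, drift, 5000), 5)
})

test_that("drift estimation needs at least two subsets and is translation-equivariant", {
  tb <- drifting_table(103, drift_none(), n_frames = 400, n_mol = 200, k = 4)
  expect_error(estimate_drift(tb, subset_frames = 500), "at least 2")

  tb2 <- drifting_table(104, drift_linear(c(0.1, -0.05)), n_frames = 1500,
                        n_mol = 800, k = 6)
  traj_a <- estimate_drift(tb2, subset_frames = 500)
  shifted <- tb2
  shifted$x_nm <- shifted$x_nm + 12345
  shifted$y_nm <- shifted$y_nm - 6789
  traj_b <- estimate_drift(shifted, subset_frames = 500)
  expect_equal(traj_a$dx_nm, traj_b$dx_nm, tolerance = 1e-9)
  expect_equal(traj_a$dy_nm, traj_b$dy_nm, tolerance = 1e-9)
})

test_that("drift correction round-trips the injected drift", {
  drift <- drift_linear(c(0.02, -0.01))
  tb <- drifting_table(105, drift, n_frames = 3000, n_mol = 1500, k = 8)
  traj <- estimate_drift(tb, subset_frames = 500)
  corrected <- apply_drift_correction(tb, traj)
  expect_equal(nrow(corrected), nrow(tb))
  # residual per-row distance to the pre-drift truth is mostly localization
  # noise; allow 2x the injected 5 nm precision (plus the drift-reference
  # offset of the first subset, which is common to all rows)
  ref <- colMeans(ectostorm:::drift_at(drift, 1:500))
  dx <- corrected$x_nm - (corrected$x_true_nm + ref[1])
  dy <- corrected$y_nm - (corrected$y_true_nm + ref[2])
  within <- sqrt(dx^2 + dy^2) <= 2 * 5 * 2
  expect_gte(mean(within), 0.95)

  # zero trajectory is the identity; applying twice shifts twice
  zero <- traj
  zero$dx_nm <- 0; zero$dy_nm <- 0
  expect_equal(apply_drift_correction(tb, zero)$x_nm, tb$x_nm)
  twice <- apply_drift_correction(corrected, traj)
  expect_equal(twice$x_nm, corrected$x_nm -
                 drift_displacement(traj, tb$frame)[, 1])
})

test_that("out-of-range frames are rejected by drift correction", {
  tb <- drifting_table(106, drift_none(), n_frames = 1000, n_mol = 500,
                       k = 5)
  traj <- estimate_drift(tb, subset_frames = 500)
  bad <- tb
  bad$frame[1] <- 5000
  expect_error(apply_drift_correction(bad, traj), "frame range")
})

test_that("channel transforms recover identity and a known affine map", {
  set.seed(41)
  pairs_id <- tibble::tibble(x_mov = runif(10, 0, 2e4),
                             y_mov = runif(10, 0, 2e4))
  pairs_id$x_ref <- pairs_id$x_mov
  pairs_id$y_ref <- pairs_id$y_mov
  tr <- fit_channel_transform(pairs_id, order = 1)
  expect_equal(unname(tr$coef_x), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(unname(tr$coef_y), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(tr$rms_nm, 1e-9)

  # rotation by 2 degrees plus a 50 nm shift
  th <- 2 * pi / 180
  pairs <- tibble::tibble(x_mov = runif(10, 0, 2e4),
                          y_mov = runif(10, 0, 2e4))
  pairs$x_ref <- cos(th) * pairs$x_mov - sin(th) * pairs$y_mov + 50
  pairs$y_ref <- sin(th) * pairs$x_mov + cos(th) * pairs$y_mov + 50
  tr2 <- fit_channel_transform(pairs, order = 1)
  expect_lt(tr2$rms_nm, 1e-6)
  expect_equal(unname(tr2$coef_x), c(50, cos(th), -sin(th)),
               tolerance = 1e-8)

  # underdetermined geometry errors out
  expect_error(fit_channel_transform(pairs[1:2, ], order = 2), "at least 6")
  colinear <- tibble::tibble(x_mov = 1:6 * 100, y_mov = 1:6 * 100,
                             x_ref = 1:6 * 100, y_ref = 1:6 * 100)
  expect_error(fit_channel_transform(colinear, order = 2), "degenerate")
})

test_that("applying a transform and its inverse is the identity", {
  set.seed(43)
  pairs <- tibble::tibble(x_mov = runif(12, 0, 2e4),
                          y_mov = runif(12, 0, 2e4))
  pairs$x_ref <- 1.001 * pairs$x_mov - 0.002 * pairs$y_mov + 30 +
    1e-8 * pairs$x_mov^2
  pairs$y_ref <- 0.0015 * pairs$x_mov + 0.999 * pairs$y_mov - 20
  tr <- fit_channel_transform(pairs, order = 2)
  tb <- loc_table(frame = 1:200, x_nm = runif(200, 0, 2e4),
                  y_nm = runif(200, 0, 2e4))
  fwd <- apply_transform(tb, tr)
  back <- apply_transform(fwd, tr, inverse = TRUE)
  expect_equal(back$x_nm, tb$x_nm, tolerance = 1e-6)
  expect_equal(back$y_nm, tb$y_nm, tolerance = 1e-6)

  # identity transform leaves the table unchanged
  id <- fit_channel_transform(tibble::tibble(
    x_mov = runif(6, 0, 1e4), y_mov = runif(6, 0, 1e4)) |>
      dplyr::mutate(x_ref = x_mov, y_ref = y_mov), order = 1)
  expect_equal(apply_transform(tb, id)$x_nm, tb$x_nm, tolerance = 1e-9)
})

test_that("a warped 488 channel registers back onto the 640 reference", {
  sc <- generate_scene(scene_params(n_cells = 2, vesicles_per_cell_mean = 10,
                                    vesicles_per_cell_sd = 0,
                                    n_fiducials = 10), seed = 61)
  warp <- warp_affine(dx_nm = 40, dy_nm = -25, rot_deg = 0.3,
                      scale = 1.0005, center_nm = c(1e4, 1e4))
  sim <- simulate_localizations(
    sc, blink_model(mean_blinks = 2),
    acquisition_config(n_frames = 1000, precision_nm = 0, warp = warp,
                       fiducial_precision_nm = 0.5),
    seed = 62)
  fid488 <- dplyr::filter(sim$fiducial_locs, channel == "488")
  fid640 <- dplyr::filter(sim$fiducial_locs, channel == "640")
  pairs <- match_fiducials(fid488, fid640)
  expect_equal(nrow(pairs), 10)
  tr <- fit_channel_transform(pairs, order = 1)
  ch488 <- dplyr::filter(sim$locs, channel == "488")
  reg <- apply_transform(ch488, tr)
  rms <- sqrt(mean((reg$x_nm - ch488$x_true_nm)^2 +
                   (reg$y_nm - ch488$y_true_nm)^2))
  expect_lt(rms, 10)
})

test_that("trajectories and transforms round-trip through structured text", {
  tb <- drifting_table(107, drift_linear(c(0.05, 0)), n_frames = 1000,
                       n_mol = 600, k = 5)
  traj <- estimate_drift(tb, subset_frames = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$dx_nm, traj$dx_nm)
  expect_equal(attr(back, "frame_range"), as.numeric(attr(traj, "frame_range")))
  expect_equal(drift_displacement(back, 1:1000),
               drift_displacement(traj, 1:1000))

  pairs <- tibble::tibble(x_mov = runif(6, 0, 1e4), y_mov = runif(6, 0, 1e4))
  pairs$x_ref <- pairs$x_mov * 1.001 + 20
  pairs$y_ref <- pairs$y_mov - 15
  tr <- fit_channel_transform(pairs)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_transform(tr, path2)
  tr2 <- read_transform(path2)
  pts <- loc_table(frame = 1:50, x_nm = runif(50, 0, 1e4),
                   y_nm = runif(50, 0, 1e4))
  expect_equal(apply_transform(pts, tr2)$x_nm, apply_transform(pts, tr)$x_nm,
               tolerance = 1e-12)
})
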