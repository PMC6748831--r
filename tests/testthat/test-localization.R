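test_that("peak detection finds isolated maxima and nothing on flat frames", {
  f <- gaussian_frame(25, 25, 12.5, 8.5, 4000, 1.3)
  pk <- detect_peaks(f, threshold = 100)
  expect_equal(nrow(pk), 1)
  expect_equal(unname(c(pk$col, pk$row)), c(13, 9))

  expect_equal(nrow(detect_peaks(matrix(1, 20, 20), threshold = 10)), 0)

  two <- gaussian_frame(30, 30, 8.5, 15.5, 4000, 1.3) +
    gaussian_frame(30, 30, 18.5, 15.5, 4000, 1.3)
  pk2 <- detect_peaks(two, threshold = 100)
  expect_equal(nrow(pk2), 2)
  expect_setequal(pk2$col, c(9, 19))

  bad <- matrix(0, 10, 10); bad[5, 5] <- NaN
  expect_error(detect_peaks(bad, 1), "non-finite")
})

test_that("Gaussian fitting recovers noiseless truth and the precision rule", {
  f <- gaussian_frame(25, 25, 12.30, 7.75, 5000, 1.2)
  fit <- fit_gaussian(f, row = 8, col = 13, pixel_size_nm = 107)
  expect_equal(fit$x_nm / 107, 12.30, tolerance = 0.01 / 12.30)
  expect_equal(fit$y_nm / 107, 7.75, tolerance = 0.01 / 7.75)
  expect_equal(fit$photons, 5000, tolerance = 1e-3)
  expect_equal(fit$sigma_nm, 1.2 * 107, tolerance = 1e-3)
  # precision = sigma / sqrt(N)
  expect_equal(fit$precision_nm, fit$sigma_nm / sqrt(fit$photons),
               tolerance = 1e-12)

  expect_error(fit_gaussian(f, row = 2, col = 13), "out of frame")
})

test_that("photon filtering is inclusive at the threshold, idempotent and monotone", {
  tb <- loc_table(frame = 1:5, x_nm = 1:5, y_nm = 1:5,
                  photons = c(1999, 2000, 2001, 500, 9000))
  kept <- filter_photons(tb)
  expect_equal(kept$photons, c(2000, 2001, 9000))
  expect_identical(filter_photons(kept), kept)
  # monotone: higher threshold gives a subset
  expect_true(all(filter_photons(tb, 5000)$photons %in% kept$photons))
  # empty in, empty out; all-above-threshold is the identity
  expect_equal(nrow(filter_photons(tb[0, ])), 0)
  expect_equal(filter_photons(tb, 0), tb)
})

test_that("consecutive-frame merging follows the one-pixel rule", {
  # same position in frames 3 and 4: one row, photons summed
  tb <- loc_table(frame = c(3, 4), x_nm = c(500, 500), y_nm = c(500, 500),
                  photons = c(2500, 2500))
  m <- merge_consecutive(tb)
  expect_equal(nrow(m), 1)
  expect_equal(m$photons, 5000)
  expect_equal(m$frame, 3)

  # a frame gap keeps rows separate
  gap <- loc_table(frame = c(1, 7), x_nm = c(500, 500), y_nm = c(500, 500))
  expect_equal(nrow(merge_consecutive(gap)), 2)

  # a 5-frame chain within one pixel collapses to a single localization
  chain <- loc_table(frame = 1:5, x_nm = 500 + c(0, 30, -30, 15, 0),
                     y_nm = 500 + c(0, -20, 10, 0, 25),
                     photons = c(2000, 3000, 2500, 2200, 2800))
  mc <- merge_consecutive(chain)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$photons, sum(chain$photons))
  expect_equal(mc$x_nm, sum(chain$x_nm * chain$photons) / sum(chain$photons))

  # a cap of 5 frames splits a 6-frame run
  run6 <- loc_table(frame = 1:6, x_nm = rep(500, 6), y_nm = rep(500, 6))
  expect_equal(nrow(merge_consecutive(run6)), 1)
  expect_equal(nrow(merge_consecutive(run6, max_frames = 5)), 2)

  # displacement beyond one pixel breaks the chain
  jump <- loc_table(frame = 1:2, x_nm = c(500, 700), y_nm = c(500, 500))
  expect_equal(nrow(merge_consecutive(jump)), 2)
})

test_that("merging never increases rows and conserves photons", {
  set.seed(31)
  n <- 300
  tb <- loc_table(frame = sort(sample.int(60, n, replace = TRUE)),
                  x_nm = runif(n, 0, 2000), y_nm = runif(n, 0, 2000),
                  photons = runif(n, 2000, 6000))
  m <- merge_consecutive(tb)
  expect_lte(nrow(m), nrow(tb))
  expect_equal(sum(m$photons), sum(tb$photons), tolerance = 1e-9)
})

test_that("rendering integrates to the localization count and scales linearly", {
  one <- loc_table(frame = 1, x_nm = 500, y_nm = 500, precision_nm = 20)
  img <- render_localizations(one, pixel_size_out_nm = 5)
  expect_equal(sum(img$intensity), 1, tolerance = 1e-6)

  two <- loc_table(frame = c(1, 1), x_nm = c(500, 500), y_nm = c(500, 500),
                   precision_nm = 20)
  img2 <- render_localizations(two, pixel_size_out_nm = 5,
                               extent_nm = c(400, 600, 400, 600))
  img1 <- render_localizations(one, pixel_size_out_nm = 5,
                               extent_nm = c(400, 600, 400, 600))
  expect_equal(img2$intensity, 2 * img1$intensity, tolerance = 1e-12)

  # FWHM of a single rendered spot is 2.355x the precision
  fine <- render_localizations(one, pixel_size_out_nm = 1)
  prof <- fine$intensity[which.max(apply(fine$intensity, 1, max)), ]
  half <- max(prof) / 2
  xs <- which(prof >= half)
  fwhm <- (max(xs) - min(xs) + 1) * fine$pixel_size_nm
  expect_equal(fwhm, 2.355 * 20, tolerance = 0.05)

  expect_error(render_localizations(one, pixel_size_out_nm = 0), "> 0")
})

test_that("frame localization recovers sparse emitters end to end", {
  set.seed(17)
  grid <- expand.grid(x = c(800, 1900, 3000), y = c(800, 1900, 3000))
  em <- tibble::tibble(x_nm = grid$x + runif(9, -100, 100),
                       y_nm = grid$y + runif(9, -100, 100))
  acq <- acquisition_config(background_photons = 2, psf_sigma_nm = 150,
                            pixel_size_nm = 107)
  sim <- simulate_frames(emitters = em, n_frames = 40, seed = 23,
                         blink = blink_model(photon_mean = 4000,
                                             photon_sdlog = 0.1,
                                             labeling_efficiency = 1),
                         acq = acq)
  locs <- localize_frames(sim, threshold = 100)
  locs <- filter_photons(locs, 2000)
  expect_gt(nrow(locs), 0)
  # each emitter recovered within 2x the reported localization precision
  d <- sqrt(ectostorm:::pdist2(em$x_nm, em$y_nm, locs$x_nm, locs$y_nm))
  tol <- 2 * matrix(locs$precision_nm, nrow(em), nrow(locs), byrow = TRUE)
  recovered <- apply(d <= pmax(tol, 5), 1, any)
  expect_gte(mean(recovered), 0.9)
})

test_that("localization tables survive the CSV dialect round trip", {
  tb <- loc_table(frame = c(2, 1, 3), x_nm = c(10.5, 20.25, 30),
                  y_nm = c(1, 2, 3), photons = c(2500, 3000, 3500))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tb, path)
  back <- read_localizations(path)
  expect_equal(back$x_nm, tb$x_nm[order(tb$frame)],
               tolerance = 1e-12, ignore_attr = TRUE)
  # ThunderSTORM-style headers are accepted
  ts <- data.frame(check.names = FALSE,
                   frame = 1:2, `x [nm]` = c(1.5, 2.5), `y [nm]` = c(3, 4),
                   `intensity [photon]` = c(2100, 2200),
                   `sigma [nm]` = c(140, 150))
  utils::write.csv(ts, path, row.names = FALSE)
  back2 <- read_localizations(path)
  expect_equal(back2$photons, c(2100, 2200))
  expect_equal(back2$x_nm, c(1.5, 2.5))
})
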