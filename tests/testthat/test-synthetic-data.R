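test_that("scene generation is deterministic and respects its geometry", {
  p <- scene_params(n_cells = 2, vesicles_per_cell_mean = 10,
                    vesicles_per_cell_sd = 1)
  s1 <- generate_scene(p, seed = 11)
  s2 <- generate_scene(p, seed = 11)
  expect_identical(s1$vesicles, s2$vesicles)
  expect_identical(s1$molecules, s2$molecules)
  expect_false(identical(s1$molecules, generate_scene(p, seed = 12)$molecules))

  # every cluster center within the vesicle radius, every molecule on the disk
  v <- s1$vesicles[match(s1$clusters$vesicle, s1$vesicles$vesicle), ]
  d_cl <- sqrt((s1$clusters$x_nm - v$x_nm)^2 + (s1$clusters$y_nm - v$y_nm)^2)
  expect_true(all(d_cl <= v$diameter_nm / 2 + 1e-9))
  vm <- s1$vesicles[match(s1$molecules$vesicle, s1$vesicles$vesicle), ]
  d_mol <- sqrt((s1$molecules$x_nm - vm$x_nm)^2 +
                (s1$molecules$y_nm - vm$y_nm)^2)
  expect_true(all(d_mol <= vm$diameter_nm / 2 + 1e-9))
  expect_true(all(s1$vesicles$diameter_nm > 0))

  # class composition is consistent with attached clusters
  tcr_ves <- unique(s1$clusters$vesicle[s1$clusters$species == "TCR"])
  partner_ves <- unique(s1$clusters$vesicle[s1$clusters$species == "CD40L"])
  tcr_only <- s1$vesicles$vesicle[s1$vesicles$class == "tcr-only"]
  expect_true(all(tcr_only %in% tcr_ves))
  expect_false(any(tcr_only %in% partner_ves))
})

test_that("scene diameter statistics converge to the configured values", {
  p <- scene_params(n_cells = 1, cell_radius_um = 30,
                    vesicles_per_cell_mean = 10000, vesicles_per_cell_sd = 0,
                    field_size_nm = c(80000, 80000),
                    membrane_molecules_per_vesicle = 1,
                    molecules_per_cluster = 1)
  sc <- generate_scene(p, seed = 21)
  n <- nrow(sc$vesicles)
  se_mean <- 5 / sqrt(n)
  expect_lt(abs(mean(sc$vesicles$diameter_nm) - 84), 3 * se_mean)
  se_sd <- 5 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(sc$vesicles$diameter_nm) - 5), 3 * se_sd)
})

test_that("double-positive fraction is recovered within its binomial CI", {
  sc <- generate_scene(scene_params(n_cells = 8), seed = 31)
  n <- nrow(sc$vesicles)
  k <- sum(sc$vesicles$class == "double-positive")
  ci <- stats::binom.test(k, n)$conf.int
  expect_gte(0.545, ci[1])
  expect_lte(0.545, ci[2])
})

test_that("a zero-vesicle scene has cells but no vesicles or clusters", {
  sc <- generate_scene(scene_params(n_cells = 3, vesicles_per_cell_mean = 0,
                                    vesicles_per_cell_sd = 0), seed = 1)
  expect_equal(nrow(sc$cells), 3)
  expect_equal(nrow(sc$vesicles), 0)
  expect_equal(nrow(sc$clusters), 0)
  expect_equal(nrow(sc$molecules), 0)
})

test_that("scene parameters are validated", {
  expect_error(scene_params(diameter_mean_nm = -5), "diameter_mean_nm")
  expect_error(scene_params(frac_double_positive = 1.2),
               "frac_double_positive")
  expect_error(scene_params(frac_double_positive = 0.8, frac_tcr_only = 0.5),
               "fractions")
})

test_that("scenes round-trip through their structured text form", {
  sc <- generate_scene(scene_params(n_cells = 1, vesicles_per_cell_mean = 5,
                                    vesicles_per_cell_sd = 0), seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_equal(back$vesicles$diameter_nm, sc$vesicles$diameter_nm)
  expect_equal(back$molecules$x_nm, sc$molecules$x_nm)
  expect_equal(back$field_size_nm, sc$field_size_nm)
})

test_that("the noiseless localization limit reproduces molecule coordinates", {
  sc <- generate_scene(scene_params(n_cells = 1, vesicles_per_cell_mean = 5,
                                    vesicles_per_cell_sd = 0), seed = 3)
  sim <- simulate_localizations(
    sc,
    blink_model(mean_blinks = 1, mean_on_frames = 1,
                labeling_efficiency = 1, photon_sdlog = 0),
    acquisition_config(n_frames = 100, precision_nm = 0), seed = 5)
  expect_equal(nrow(sim$locs), nrow(sc$molecules))
  ord <- order(sim$locs$molecule)
  expect_equal(sim$locs$x_nm[ord], sc$molecules$x_nm)
  expect_equal(sim$locs$y_nm[ord], sc$molecules$y_nm)
})

test_that("localization counts match the blink model expectation", {
  sc <- generate_scene(scene_params(n_cells = 1, vesicles_per_cell_mean = 20,
                                    vesicles_per_cell_sd = 0), seed = 3)
  n_mol <- nrow(sc$molecules)
  eff <- 0.7; lambda <- 3
  sim <- simulate_localizations(
    sc, blink_model(mean_blinks = lambda, mean_on_frames = 1,
                    labeling_efficiency = eff),
    acquisition_config(n_frames = 2000), seed = 9)
  # per-molecule count X = Bern(eff) * (1 + Pois(lambda - 1))
  ex <- eff * lambda
  vx <- eff * (lambda^2 + lambda - 1) - (eff * lambda)^2
  expect_lt(abs(nrow(sim$locs) - n_mol * ex), 3 * sqrt(n_mol * vx))
})

test_that("localization simulation is deterministic and sorted by frame", {
  sc <- generate_scene(scene_params(n_cells = 1, vesicles_per_cell_mean = 5,
                                    vesicles_per_cell_sd = 0), seed = 3)
  s1 <- simulate_localizations(sc, seed = 4,
                               acq = acquisition_config(n_frames = 200))
  s2 <- simulate_localizations(sc, seed = 4,
                               acq = acquisition_config(n_frames = 200))
  expect_identical(s1$locs, s2$locs)
  expect_identical(s1$fiducial_locs, s2$fiducial_locs)
  by_ch <- split(s1$locs$frame, s1$locs$channel)
  expect_true(all(vapply(by_ch, function(f) !is.unsorted(f), logical(1))))
  # fiducials appear in every frame of every channel
  fid <- s1$fiducial_locs
  counts <- table(fid$channel, fid$frame)
  expect_true(all(counts == nrow(sc$fiducials)))
})

test_that("frame simulation conserves photons and centers symmetric PSFs", {
  em <- tibble::tibble(x_nm = 1605, y_nm = 1605)  # center of a 30x30 field
  sim <- simulate_frames(emitters = em, n_frames = 1, seed = 2,
                         blink = blink_model(mean_blinks = 1,
                                             mean_on_frames = 1,
                                             labeling_efficiency = 1,
                                             photon_sdlog = 0,
                                             photon_mean = 5000),
                         acq = acquisition_config(background_photons = 0))
  f <- sim$frames[, , 1]
  expect_equal(sum(f), 5000, tolerance = 1e-7)
  # intensity-weighted centroid at the emitter position
  nx <- ncol(f); ny <- nrow(f)
  cx <- sum(t(f) * (seq_len(nx) - 0.5)) / sum(f) * sim$pixel_size_nm
  cy <- sum(f * (seq_len(ny) - 0.5)) / sum(f) * sim$pixel_size_nm
  expect_equal(cx, 1605, tolerance = 1e-5)
  expect_equal(cy, 1605, tolerance = 1e-5)
})

test_that("oversized fields are refused by the frame simulator", {
  em <- tibble::tibble(x_nm = 20000, y_nm = 20000)
  expect_error(simulate_frames(emitters = em, n_frames = 1, seed = 1),
               "budget")
})

test_that("cytometry panels are deterministic with an exact zero-noise ladder", {
  p <- cytometry_params(ladder_cv = 0, event_cv = 0)
  s1 <- simulate_cytometry(p, seed = 5)
  s2 <- simulate_cytometry(p, seed = 5)
  expect_identical(s1$events, s2$events)
  cal <- fit_mesf_curve(s1$ladder, blank = s1$blank_intensity)
  expect_equal(glance(cal)$r_squared, 1, tolerance = 1e-12)
  # round trip: ladder intensities map back to their assigned MESF exactly
  back <- intensity_to_molecules(cal, s1$ladder$intensity)
  expect_equal(as.numeric(back), s1$ladder$mesf, tolerance = 1e-9)
})

test_that("proteome simulation flags its enriched set and is deterministic", {
  p <- proteome_params(n_proteins = 50, frac_enriched = 0.2, effect_fc = 4,
                       noise_sdlog = 0)
  s1 <- simulate_proteome(p, seed = 2)
  expect_identical(s1, simulate_proteome(p, seed = 2))
  truth <- attr(s1, "truth")
  expect_equal(sum(truth$enriched), 10)
  wide <- tidyr::pivot_wider(s1, names_from = "condition",
                             values_from = "intensity")
  fc <- wide$plus / wide$minus
  expect_equal(unique(round(fc[truth$enriched[match(wide$protein,
                                                    truth$protein)]], 9)), 4)
})
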