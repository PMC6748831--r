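#' Parameters for a simulated flow-cytometry transfer panel
#'
#' The panel mimics the BSLB transfer experiment: for each marker a true
#' number of molecules per object is split between the bead (BSLB) and the
#' T-cell population by the true transfer fraction; event intensities follow
#' the same proportional MESF response curve as the bead ladder, with
#' log-normal spread, on top of an isotype background.
#'
#' @param markers Tibble with columns `marker`, `total_molecules`,
#'   `transfer_fraction`.
#' @param dye_ratio AF647 dye-to-antibody ratio (MESF per bound antibody).
#' @param response_scale Intensity units per MESF (the response is
#'   proportional, i.e. log-log slope 1).
#' @param ladder_mesf Assigned MESF values of the bead ladder (>= 3, strictly
#'   increasing).
#' @param ladder_cv Log-sd of multiplicative ladder noise (0 = exactly
#'   log-log linear).
#' @param event_cv Log-sd of multiplicative event noise.
#' @param isotype_mean Mean isotype/background intensity.
#' @param n_events Events per marker per population.
#' @param blank_intensity Blank-bead intensity subtracted before calibration.
#' @return A validated parameter list.
#' @export
cytometry_params <- function(markers = tibble(
                               marker = c("TCR", "CD40L", "ICOS"),
                               total_molecules = c(30000, 5000, 12000),
                               transfer_fraction = c(0.03, 0.30, 0.12)),
                             dye_ratio = 3, response_scale = 0.02,
                             ladder_mesf = c(5e3, 2e4, 8e4, 3e5, 1.2e6),
                             ladder_cv = 0, event_cv = 0.2,
                             isotype_mean = 20, n_events = 2000,
                             blank_intensity = 5) {
  assert_cols(markers, c("marker", "total_molecules", "transfer_fraction"),
              "markers")
  stopifnot(all(markers$total_molecules >= 0),
            all(markers$transfer_fraction >= 0),
            all(markers$transfer_fraction <= 1),
            length(ladder_mesf) >= 3, all(diff(ladder_mesf) > 0),
            dye_ratio > 0, response_scale > 0, ladder_cv >= 0, event_cv >= 0)
  list(markers = markers, dye_ratio = dye_ratio,
       response_scale = response_scale, ladder_mesf = ladder_mesf,
       ladder_cv = ladder_cv, event_cv = event_cv,
       isotype_mean = isotype_mean, n_events = as.integer(n_events),
       blank_intensity = blank_intensity)
}

#' Simulate a flow-cytometry panel with an MESF ladder
#'
#' @param params A [cytometry_params()] list.
#' @param seed Integer seed.
#' @return A list of class `cytometry_panel`: `events` (marker, population,
#'   kind = stain/isotype, intensity), `ladder` (intensity, mesf),
#'   `blank_intensity`, `dye_ratio`, and the ground truth (`truth`: molecules
#'   per population per marker).
#' @export
simulate_cytometry <- function(params = cytometry_params(), seed = 1) {
  p <- params
  with_seed(seed, {
    ladder_noise <- if (p$ladder_cv > 0) {
      rlnorm(length(p$ladder_mesf), -p$ladder_cv^2 / 2, p$ladder_cv)
    } else rep(1, length(p$ladder_mesf))
    ladder <- tibble(
      intensity = p$blank_intensity +
        p$response_scale * p$ladder_mesf * ladder_noise,
      mesf = p$ladder_mesf
    )
    rows <- list(); truth_rows <- list()
    for (i in seq_len(nrow(p$markers))) {
      m <- p$markers[i, ]
      mol <- c(BSLB = m$total_molecules * m$transfer_fraction,
               Tcell = m$total_molecules * (1 - m$transfer_fraction))
      for (pop in names(mol)) {
        mean_specific <- p$response_scale * mol[[pop]] * p$dye_ratio
        noise <- if (p$event_cv > 0) {
          rlnorm(p$n_events, -p$event_cv^2 / 2, p$event_cv)
        } else rep(1, p$n_events)
        bg <- if (p$event_cv > 0) {
          rlnorm(p$n_events, -p$event_cv^2 / 2, p$event_cv)
        } else rep(1, p$n_events)
        iso <- if (p$event_cv > 0) {
          rlnorm(p$n_events, -p$event_cv^2 / 2, p$event_cv)
        } else rep(1, p$n_events)
        rows[[length(rows) + 1L]] <- tibble(
          marker = m$marker, population = pop,
          kind = "stain",
          intensity = mean_specific * noise + p$isotype_mean * bg)
        rows[[length(rows) + 1L]] <- tibble(
          marker = m$marker, population = pop,
          kind = "isotype", intensity = p$isotype_mean * iso)
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          marker = m$marker, population = pop, molecules = mol[[pop]],
          transfer_fraction = m$transfer_fraction)
      }
    }
    structure(list(events = bind_rows(rows), ladder = ladder,
                   blank_intensity = p$blank_intensity,
                   dye_ratio = p$dye_ratio, truth = bind_rows(truth_rows),
                   params = p),
              class = "cytometry_panel")
  })
}
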