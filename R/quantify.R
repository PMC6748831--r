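#' Fit an MESF calibration curve
#'
#' Least-squares fit of `log10(MESF)` on `log10(intensity - blank)` over the
#' bead ladder. Quantum MESF beads carry assigned molecule-equivalents of
#' soluble fluorochrome, so the fitted curve converts measured intensities to
#' absolute dye counts.
#'
#' @param ladder Tibble with columns `intensity`, `mesf` (>= 3 rows, both
#'   strictly increasing).
#' @param blank Blank-bead intensity subtracted from all intensities first.
#' @return An object of class `mesf_calibration`: slope, intercept, R
#'   squared, and the valid (blank-corrected) intensity range.
#' @export
fit_mesf_curve <- function(ladder, blank = 0) {
  assert_cols(ladder, c("intensity", "mesf"), "ladder")
  if (nrow(ladder) < 3) abort("the MESF ladder needs at least 3 populations")
  if (any(diff(ladder$mesf) <= 0)) abort("MESF values must be strictly increasing")
  corrected <- ladder$intensity - blank
  if (any(corrected <= 0)) abort("ladder intensities at or below blank")
  if (any(diff(corrected) <= 0)) {
    abort("ladder intensities must increase with MESF")
  }
  fit <- lm(log10(ladder$mesf) ~ log10(corrected))
  y <- log10(ladder$mesf)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, blank = blank,
                 intensity_range = range(corrected)),
            class = "mesf_calibration")
}

#' Convert intensities to absolute molecule numbers
#'
#' Applies the calibration curve and divides by the dye:antibody ratio so the
#' result is antibody-binding sites rather than dye molecules. Conversions
#' outside the calibrated intensity range are flagged with a warning.
#'
#' @param calibration An `mesf_calibration`.
#' @param intensity Raw intensities (the calibration blank is subtracted).
#' @param dye_ratio AF647:antibody ratio (default 1 = report MESF).
#' @return Numeric vector of molecules, with `n_out_of_range` attribute.
#' @export
intensity_to_molecules <- function(calibration, intensity, dye_ratio = 1) {
  if (dye_ratio <= 0) abort("`dye_ratio` must be > 0")
  corrected <- intensity - calibration$blank
  if (any(corrected <= 0)) abort("intensity at or below the calibration blank")
  mesf <- 10^(calibration$intercept + calibration$slope * log10(corrected))
  out_of_range <- corrected < calibration$intensity_range[1] |
    corrected > calibration$intensity_range[2]
  if (any(out_of_range)) {
    warn(sprintf("%d intensit(ies) outside the calibrated range",
                 sum(out_of_range)))
  }
  structure(mesf / dye_ratio, n_out_of_range = sum(out_of_range))
}

#' Percent synaptic transfer from isotype-corrected GMFIs
#'
#' `100 * GMFI_BSLB / (GMFI_BSLB + GMFI_Tcell)` after subtracting the isotype
#' control GMFI from each population, clamping negative corrected values to
#' zero (transfer cannot be negative). Vectorized over markers.
#'
#' @param gmfi_bslb,gmfi_tcell Raw population GMFIs (>= 0).
#' @param isotype_bslb,isotype_tcell Isotype-control GMFIs per population.
#' @return Percent transfer in `[0, 100]`; errors if both corrected GMFIs of
#'   any entry are zero (the ratio is undefined).
#' @export
#' @examples
#' percent_transfer(35, 75, isotype_bslb = 5, isotype_tcell = 5)  # 30
percent_transfer <- function(gmfi_bslb, gmfi_tcell,
                             isotype_bslb = 0, isotype_tcell = 0) {
  if (any(c(gmfi_bslb, gmfi_tcell) < 0)) abort("GMFIs must be >= 0")
  cb <- pmax(gmfi_bslb - isotype_bslb, 0)
  ct <- pmax(gmfi_tcell - isotype_tcell, 0)
  if (any(cb + ct == 0)) {
    abort("both corrected GMFIs are zero; percent transfer undefined")
  }
  100 * cb / (cb + ct)
}

#' Molecular site density on a sphere
#'
#' Density of molecules over the surface of a sphere of the given diameter
#' (surface area `pi * d^2`), as used to titrate ligand densities on 5 um
#' bead-supported bilayers.
#'
#' @param molecules Molecule count (>= 0).
#' @param sphere_diameter_um Sphere diameter in micrometers (> 0).
#' @return Density in molecules per square micrometer.
#' @export
#' @examples
#' site_density(7854, 5)  # 100 molecules / um^2
site_density <- function(molecules, sphere_diameter_um) {
  if (any(sphere_diameter_um <= 0)) abort("diameter must be > 0")
  molecules / (pi * sphere_diameter_um^2)
}

#' Total membrane surface area of released vesicles
#'
#' `n` spheres of diameter `d` nm have total surface area
#' `n * pi * (d / 1000)^2` square micrometers.
#'
#' @param d_nm Mean vesicle diameter in nm (> 0).
#' @param n Number of vesicles (>= 0).
#' @return Total area in square micrometers.
#' @export
#' @examples
#' se_total_area(84, 37)  # ~0.82 um^2 released per synapse
se_total_area <- function(d_nm, n) {
  if (any(d_nm <= 0)) abort("diameter must be > 0")
  if (any(n < 0)) abort("vesicle count must be >= 0")
  n * pi * (d_nm / 1000)^2
}

#' Surface density of a trimeric ligand on vesicles
#'
#' @param molecules Monomer count.
#' @param area_um2 Membrane area in square micrometers (> 0).
#' @param per_trimer Monomers per functional unit (default 3 for CD40L
#'   trimers).
#' @return Trimers (or chosen units) per square micrometer.
#' @export
se_density <- function(molecules, area_um2, per_trimer = 3) {
  if (any(area_um2 <= 0)) abort("area must be > 0")
  (molecules / per_trimer) / area_um2
}

#' Vesicle area as a fraction of the cell surface
#'
#' The comparison cell surface area is an explicit assumption supplied by the
#' caller (a resting T cell is on the order of a few hundred square
#' micrometers).
#'
#' @param se_area_um2 Total vesicle area.
#' @param cell_area_um2 Assumed cell surface area (> 0).
#' @return Percentage of the cell surface.
#' @export
fraction_of_cell_surface <- function(se_area_um2, cell_area_um2) {
  if (any(cell_area_um2 <= 0)) abort("cell area must be > 0")
  100 * se_area_um2 / cell_area_um2
}

#' Cytokine-array fold changes
#'
#' Each analyte is spotted in duplicate; its value is the mean of the two
#' spots divided by the mean of the positive-control spots of the same array
#' (correcting between-array exposure differences), and the fold change
#' normalizes each condition to the control condition. Analytes without
#' exactly two spots in a condition are flagged and excluded.
#'
#' @param spots Tibble with columns `condition`, `analyte`, `intensity`,
#'   `type` ("analyte" or "positive").
#' @param control_condition Name of the reference condition.
#' @return Tibble (analyte, condition, value, fold_change) with a
#'   `flagged` attribute naming excluded analyte/condition pairs.
#' @export
cytokine_fold_change <- function(spots, control_condition) {
  assert_cols(spots, c("condition", "analyte", "intensity", "type"), "spots")
  if (!control_condition %in% spots$condition) {
    abort("control condition not present in `spots`")
  }
  pos <- summarise(group_by(filter(spots, .data$type == "positive"),
                            .data$condition),
                   pos_mean = mean(.data$intensity), .groups = "drop")
  an <- summarise(group_by(filter(spots, .data$type == "analyte"),
                           .data$condition, .data$analyte),
                  n_spots = dplyr::n(), value_raw = mean(.data$intensity),
                  .groups = "drop")
  flagged <- an[an$n_spots != 2L, c("condition", "analyte")]
  an <- an[an$n_spots == 2L, , drop = FALSE]
  an <- left_join(an, pos, by = "condition")
  an$value <- an$value_raw / an$pos_mean
  ctrl <- an[an$condition == control_condition, c("analyte", "value")]
  names(ctrl)[2] <- "control_value"
  out <- left_join(an, ctrl, by = "analyte")
  out$fold_change <- out$value / out$control_value
  out <- out[, c("analyte", "condition", "value", "fold_change")]
  attr(out, "flagged") <- flagged
  out
}
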