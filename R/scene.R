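#' Parameters for a synthetic synaptic-ectosome scene
#'
#' Defaults emulate the study conditions of the dSTORM experiments: sub-100 nm
#' vesicles (diameter 84 +/- 5 nm) scattered in cell-sized synaptic footprints
#' at roughly 36 +/- 3 vesicles per cell, carrying a membrane glycan label
#' (WGA/CD81), a TCR microcluster and, on a configurable fraction of vesicles,
#' a partner receptor. Co-clustered partners (ICOS, BST2) share the TCR
#' cluster position; CD40L clusters are laterally offset with mean 150 nm,
#' truncated so the cluster stays on the vesicle (small vesicles place CD40L
#' at the rim).
#'
#' @param n_cells Number of synaptic footprints.
#' @param field_size_nm Field of view, c(width, height) in nm.
#' @param cell_radius_um Footprint radius in micrometers.
#' @param vesicles_per_cell_mean,vesicles_per_cell_sd Normal distribution of
#'   the per-cell vesicle count (rounded, truncated at 0).
#' @param diameter_mean_nm,diameter_sd_nm Normal distribution of vesicle
#'   diameters (nm, truncated at > 0).
#' @param partner Partner species paired with TCR: "CD40L" (offset) or a
#'   co-clustered species such as "ICOS" or "BST2".
#' @param frac_double_positive Fraction of vesicles carrying both TCR and the
#'   partner.
#' @param frac_tcr_only Fraction carrying TCR only; the default splits the
#'   remainder equally between TCR-only and partner-only.
#' @param partner_offset_nm,partner_offset_sd_nm Lateral offset (nm) of CD40L
#'   cluster centers from the vesicle center; ignored for co-clustered
#'   partners.
#' @param cluster_sigma_nm Gaussian spread of receptor clusters (nm).
#' @param molecules_per_cluster Molecules per receptor cluster.
#' @param membrane_molecules_per_vesicle Membrane-label molecules per vesicle
#'   (uniform over the vesicle disk).
#' @param reference_species Membrane reference label name (default "CD81").
#' @param n_fiducials Number of always-on fiducial beads in the field.
#' @return A named list of validated scene parameters.
#' @export
scene_params <- function(n_cells = 4,
                         field_size_nm = c(20000, 20000),
                         cell_radius_um = 2.5,
                         vesicles_per_cell_mean = 36,
                         vesicles_per_cell_sd = 3,
                         diameter_mean_nm = 84,
                         diameter_sd_nm = 5,
                         partner = "CD40L",
                         frac_double_positive = 0.545,
                         frac_tcr_only = NULL,
                         partner_offset_nm = 150,
                         partner_offset_sd_nm = 10,
                         cluster_sigma_nm = 10,
                         molecules_per_cluster = 30,
                         membrane_molecules_per_vesicle = 40,
                         reference_species = "CD81",
                         n_fiducials = 8) {
  assert_number(n_cells, "n_cells", lower = 1)
  assert_number(cell_radius_um, "cell_radius_um", lower = 0, strict = TRUE)
  assert_number(vesicles_per_cell_mean, "vesicles_per_cell_mean", lower = 0)
  assert_number(vesicles_per_cell_sd, "vesicles_per_cell_sd", lower = 0)
  assert_number(diameter_mean_nm, "diameter_mean_nm", lower = 0, strict = TRUE)
  assert_number(diameter_sd_nm, "diameter_sd_nm", lower = 0)
  assert_number(frac_double_positive, "frac_double_positive", 0, 1)
  if (is.null(frac_tcr_only)) frac_tcr_only <- (1 - frac_double_positive) / 2
  assert_number(frac_tcr_only, "frac_tcr_only", 0, 1)
  if (frac_double_positive + frac_tcr_only > 1 + 1e-12) {
    abort("class fractions exceed 1")
  }
  assert_number(partner_offset_nm, "partner_offset_nm", lower = 0)
  assert_number(cluster_sigma_nm, "cluster_sigma_nm", lower = 0, strict = TRUE)
  list(n_cells = as.integer(n_cells), field_size_nm = field_size_nm,
       cell_radius_um = cell_radius_um,
       vesicles_per_cell_mean = vesicles_per_cell_mean,
       vesicles_per_cell_sd = vesicles_per_cell_sd,
       diameter_mean_nm = diameter_mean_nm, diameter_sd_nm = diameter_sd_nm,
       partner = partner,
       frac_double_positive = frac_double_positive,
       frac_tcr_only = frac_tcr_only,
       partner_offset_nm = partner_offset_nm,
       partner_offset_sd_nm = partner_offset_sd_nm,
       cluster_sigma_nm = cluster_sigma_nm,
       molecules_per_cluster = as.integer(molecules_per_cluster),
       membrane_molecules_per_vesicle =
         as.integer(membrane_molecules_per_vesicle),
       reference_species = reference_species,
       n_fiducials = as.integer(n_fiducials))
}

# Species -> acquisition channel, mirroring the three-laser layout:
# membrane label on 561, TCR on 488, the partner mAb on 640 (reference).
species_channel <- function(species, reference_species, partner) {
  ch <- rep("640", length(species))
  ch[species == reference_species | species == "WGA"] <- "561"
  ch[species == "TCR"] <- "488"
  ch
}

#' Generate a ground-truth synaptic-ectosome scene
#'
#' Draws cells, vesicles, protein clusters, individual molecule positions and
#' fiducial beads. Every molecule lies inside its vesicle's disk and every
#' cluster center lies within the vesicle radius. The same seed reproduces the
#' scene bit-for-bit.
#'
#' @param params A parameter list from [scene_params()].
#' @param seed Integer seed; the scene is a pure function of (params, seed).
#' @return An object of class `se_scene`: a list of tibbles `cells`,
#'   `vesicles`, `clusters`, `molecules`, `fiducials`, plus `field_size_nm`
#'   and the parameters used.
#' @export
#' @examples
#' sc <- generate_scene(scene_params(n_cells = 1), seed = 1)
#' nrow(sc$vesicles)
generate_scene <- function(params = scene_params(), seed = 1) {
  p <- params
  with_seed(seed, {
    r_cell_nm <- p$cell_radius_um * 1000
    cells <- tibble(
      cell = seq_len(p$n_cells),
      cx_nm = runif(p$n_cells, r_cell_nm, p$field_size_nm[1] - r_cell_nm),
      cy_nm = runif(p$n_cells, r_cell_nm, p$field_size_nm[2] - r_cell_nm),
      radius_um = p$cell_radius_um
    )

    n_ves <- pmax(0L, as.integer(round(rnorm(
      p$n_cells, p$vesicles_per_cell_mean, p$vesicles_per_cell_sd))))
    ves_list <- vector("list", p$n_cells)
    for (i in seq_len(p$n_cells)) {
      k <- n_ves[i]
      if (k == 0L) next
      d <- rnorm(k, p$diameter_mean_nm, p$diameter_sd_nm)
      while (any(d <= 0)) d[d <= 0] <- rnorm(sum(d <= 0), p$diameter_mean_nm,
                                             p$diameter_sd_nm)
      th <- runif(k, 0, 2 * pi)
      rr <- (r_cell_nm - d / 2) * sqrt(runif(k))
      cls <- sample(c("double-positive", "tcr-only", "partner-only"), k,
                    replace = TRUE,
                    prob = c(p$frac_double_positive, p$frac_tcr_only,
                             1 - p$frac_double_positive - p$frac_tcr_only))
      ves_list[[i]] <- tibble(
        cell = i,
        x_nm = cells$cx_nm[i] + rr * cos(th),
        y_nm = cells$cy_nm[i] + rr * sin(th),
        diameter_nm = d, class = cls
      )
    }
    vesicles <- bind_rows(ves_list)
    if (nrow(vesicles)) {
      vesicles <- mutate(vesicles, vesicle = row_number(),
                         .before = 1L)
    } else {
      vesicles <- tibble(vesicle = integer(), cell = integer(),
                         x_nm = numeric(), y_nm = numeric(),
                         diameter_nm = numeric(), class = character())
    }

    clusters <- make_clusters(vesicles, p)
    molecules <- make_molecules(vesicles, clusters, p)

    fiducials <- tibble(
      fiducial = seq_len(p$n_fiducials),
      x_nm = runif(p$n_fiducials, 0, p$field_size_nm[1]),
      y_nm = runif(p$n_fiducials, 0, p$field_size_nm[2])
    )

    structure(list(cells = cells, vesicles = vesicles, clusters = clusters,
                   molecules = molecules, fiducials = fiducials,
                   field_size_nm = p$field_size_nm, params = p, seed = seed),
              class = "se_scene")
  })
}

# Receptor and membrane clusters for every vesicle. Co-clustered partners sit
# on the TCR cluster center; CD40L is displaced with mean 150 nm, capped at
# the vesicle radius so the cluster center stays on the vesicle.
make_clusters <- function(vesicles, p) {
  empty <- tibble(cluster = integer(), vesicle = integer(),
                  species = character(), x_nm = numeric(), y_nm = numeric(),
                  sigma_nm = numeric(), n_molecules = integer(),
                  kind = character())
  if (!nrow(vesicles)) return(empty)
  rows <- vector("list", nrow(vesicles))
  for (i in seq_len(nrow(vesicles))) {
    v <- vesicles[i, ]
    rad <- v$diameter_nm / 2
    out <- list(tibble(vesicle = v$vesicle, species = p$reference_species,
                       x_nm = v$x_nm, y_nm = v$y_nm, sigma_nm = rad,
                       n_molecules = p$membrane_molecules_per_vesicle,
                       kind = "membrane"))
    has_tcr <- v$class %in% c("double-positive", "tcr-only")
    has_partner <- v$class %in% c("double-positive", "partner-only")
    tcr_xy <- clamp_to_disk(v$x_nm + rnorm(1, 0, 3), v$y_nm + rnorm(1, 0, 3),
                            v$x_nm, v$y_nm, rad)
    if (has_tcr) {
      out <- c(out, list(tibble(vesicle = v$vesicle, species = "TCR",
                                x_nm = tcr_xy[1], y_nm = tcr_xy[2],
                                sigma_nm = p$cluster_sigma_nm,
                                n_molecules = p$molecules_per_cluster,
                                kind = "receptor")))
    }
    if (has_partner) {
      if (identical(p$partner, "CD40L")) {
        off <- max(0, rnorm(1, p$partner_offset_nm, p$partner_offset_sd_nm))
        off <- min(off, rad)  # rim placement for vesicles smaller than offset
        th <- runif(1, 0, 2 * pi)
        cx <- v$x_nm + off * cos(th); cy <- v$y_nm + off * sin(th)
      } else {
        xy <- clamp_to_disk(tcr_xy[1] + rnorm(1, 0, 3),
                            tcr_xy[2] + rnorm(1, 0, 3),
                            v$x_nm, v$y_nm, rad)
        cx <- xy[1]; cy <- xy[2]
      }
      out <- c(out, list(tibble(vesicle = v$vesicle, species = p$partner,
                                x_nm = cx, y_nm = cy,
                                sigma_nm = p$cluster_sigma_nm,
                                n_molecules = p$molecules_per_cluster,
                                kind = "receptor")))
    }
    rows[[i]] <- bind_rows(out)
  }
  out <- bind_rows(rows)
  mutate(out, cluster = row_number(), .before = 1L)
}

clamp_to_disk <- function(x, y, cx, cy, r) {
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  if (d <= r) return(c(x, y))
  c(cx + (x - cx) * r / d, cy + (y - cy) * r / d)
}

# Molecule positions: uniform over the vesicle disk for membrane labels,
# Gaussian about the cluster center (rejection-sampled to stay on the vesicle
# disk) for receptor clusters.
make_molecules <- function(vesicles, clusters, p) {
  empty <- tibble(molecule = integer(), cluster = integer(),
                  vesicle = integer(), species = character(),
                  channel = character(), x_nm = numeric(), y_nm = numeric())
  if (!nrow(clusters)) return(empty)
  ves_idx <- match(clusters$vesicle, vesicles$vesicle)
  rows <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    v <- vesicles[ves_idx[i], ]
    rad <- v$diameter_nm / 2
    n <- cl$n_molecules
    if (cl$kind == "membrane") {
      th <- runif(n, 0, 2 * pi); rr <- rad * sqrt(runif(n))
      x <- v$x_nm + rr * cos(th); y <- v$y_nm + rr * sin(th)
    } else {
      x <- numeric(0); y <- numeric(0)
      while (length(x) < n) {
        m <- 2L * (n - length(x)) + 8L
        cx <- rnorm(m, cl$x_nm, cl$sigma_nm)
        cy <- rnorm(m, cl$y_nm, cl$sigma_nm)
        keep <- (cx - v$x_nm)^2 + (cy - v$y_nm)^2 <= rad^2
        x <- c(x, cx[keep]); y <- c(y, cy[keep])
      }
      x <- x[seq_len(n)]; y <- y[seq_len(n)]
    }
    rows[[i]] <- tibble(cluster = cl$cluster, vesicle = cl$vesicle,
                        species = cl$species, x_nm = x, y_nm = y)
  }
  out <- bind_rows(rows)
  out$channel <- species_channel(out$species, p$reference_species, p$partner)
  mutate(out, molecule = row_number(), .before = 1L)
}

#' @export
print.se_scene <- function(x, ...) {
  cat(sprintf(
    "<se_scene> %d cell(s), %d vesicle(s), %d cluster(s), %d molecule(s)\n",
    nrow(x$cells), nrow(x$vesicles), nrow(x$clusters), nrow(x$molecules)))
  cat(sprintf("  field: %g x %g nm; seed %s\n", x$field_size_nm[1],
              x$field_size_nm[2], x$seed))
  invisible(x)
}

#' Write / read a scene as structured text (JSON)
#'
#' @param scene An `se_scene`.
#' @param path Output file path.
#' @return `write_scene` returns `path` invisibly; `read_scene` returns the
#'   reconstructed `se_scene`.
#' @export
write_scene <- function(scene, path) {
  payload <- list(cells = scene$cells, vesicles = scene$vesicles,
                  clusters = scene$clusters, molecules = scene$molecules,
                  fiducials = scene$fiducials,
                  field_size_nm = scene$field_size_nm,
                  params = scene$params, seed = scene$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("cells", "vesicles", "clusters", "molecules", "fiducials")) {
    raw[[nm]] <- as_tibble(raw[[nm]])
  }
  raw$field_size_nm <- as.numeric(raw$field_size_nm)
  structure(raw, class = "se_scene")
}
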