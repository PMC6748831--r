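# Density-based spatial clustering (DBSCAN-style) with grid-hashed region
# queries. A point is core if its eps-neighborhood (including itself) holds at
# least min_pts points; clusters are grown from core points, border points
# join the first cluster that reaches them, and remaining points are noise
# (cluster 0).
dbscan_points <- function(x, y, eps, min_pts) {
  n <- length(x)
  if (!n) return(integer(0))
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy, sep = ",")
  cell_of <- split(seq_len(n), key)
  neighbor_cells <- function(i) {
    kx <- cx[i]; ky <- cy[i]
    keys <- as.vector(outer(kx + (-1:1), ky + (-1:1), paste, sep = ","))
    unlist(cell_of[keys], use.names = FALSE)
  }
  eps2 <- eps^2
  region <- function(i) {
    cand <- neighbor_cells(i)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps2]
  }
  cluster <- rep(NA_integer_, n)   # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    nb <- region(i)
    if (length(nb) < min_pts) { cluster[i] <- 0L; next }
    cl <- cl + 1L
    cluster[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(cluster[j]) && cluster[j] != 0L) next
      unvisited <- is.na(cluster[j])
      cluster[j] <- cl
      if (unvisited) {
        nb_j <- region(j)
        if (length(nb_j) >= min_pts) {
          queue <- c(queue, nb_j[is.na(cluster[nb_j]) | cluster[nb_j] == 0L])
        }
      }
    }
  }
  cluster
}

#' Segment vesicles from the membrane-reference channel
#'
#' Density-based clustering (radius `eps`, minimum neighbor count `min_pts`)
#' of reference-channel localizations; noise points are excluded. Each
#' cluster becomes one candidate synaptic ectosome with a centroid and an
#' FWHM diameter estimate.
#'
#' @param reference_table Drift/registration-corrected localization tibble of
#'   the membrane label (WGA or CD81).
#' @param eps Clustering radius in nm (default 50).
#' @param min_pts Minimum points in an eps-neighborhood (default 5).
#' @param precision_nm Rendering precision for diameter estimation; defaults
#'   to the table's `precision_nm` column.
#' @return A tibble of class `vesicle_set`: one row per vesicle with `id`,
#'   `x_nm`, `y_nm` (centroid), `n_ref` (member count), `diameter_nm`,
#'   `diameter_flagged`; the member row indices ride along as a list column
#'   `members`.
#' @export
segment_vesicles <- function(reference_table, eps = 50, min_pts = 5,
                             precision_nm = NULL) {
  if (!nrow(reference_table)) {
    out <- tibble(id = integer(), x_nm = numeric(), y_nm = numeric(),
                  n_ref = integer(), diameter_nm = numeric(),
                  diameter_flagged = logical(), members = list())
    class(out) <- c("vesicle_set", class(out))
    return(out)
  }
  assert_cols(reference_table, c("x_nm", "y_nm"), "reference_table")
  prec <- precision_nm %||% reference_table$precision_nm %||% 10
  prec <- rep(prec, length.out = nrow(reference_table))
  cl <- dbscan_points(reference_table$x_nm, reference_table$y_nm, eps,
                      min_pts)
  ids <- sort(unique(cl[cl > 0L]))
  rows <- lapply(seq_along(ids), function(k) {
    idx <- which(cl == ids[k])
    xs <- reference_table$x_nm[idx]; ys <- reference_table$y_nm[idx]
    est <- fwhm_diameter(xs, ys, prec[idx])
    tibble(id = k, x_nm = mean(xs), y_nm = mean(ys), n_ref = length(idx),
           diameter_nm = est$diameter_nm, diameter_flagged = est$flagged,
           members = list(idx))
  })
  out <- bind_rows(rows)
  class(out) <- c("vesicle_set", class(out))
  out
}

# FWHM of the radially averaged rendered intensity profile about the
# centroid. The angular average of a unit Gaussian at centroid distance d is
# proportional to exp(-(r-d)^2 / 2s^2) * I0(r d / s^2) (computed with the
# exponentially scaled Bessel for stability).
fwhm_diameter <- function(xs, ys, prec) {
  cx <- mean(xs); cy <- mean(ys)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  smax <- max(prec)
  rmax <- max(d) + 6 * smax
  r <- seq(0, rmax, length.out = 512L)
  prof <- numeric(length(r))
  for (i in seq_along(d)) {
    s2 <- prec[i]^2
    prof <- prof + exp(-(r - d[i])^2 / (2 * s2)) *
      besselI(r * d[i] / s2, 0, expon.scaled = TRUE) / s2
  }
  half <- max(prof) / 2
  above <- which(prof >= half)
  k <- max(above)
  r_half <- if (k < length(r)) {
    r[k] + (prof[k] - half) / (prof[k] - prof[k + 1]) * (r[k + 1] - r[k])
  } else r[k]
  flagged <- max(d) < 1e-9  # all points coincident: rendering-limited width
  list(diameter_nm = 2 * r_half, flagged = flagged)
}

#' FWHM diameter of one cluster of localizations
#'
#' @param xs,ys Member coordinates (nm).
#' @param precision_nm Per-member rendering precision (nm, recycled).
#' @return Diameter in nm; degenerate clusters (all points coincident) return
#'   the rendering-limited FWHM (2.355 x precision) with attribute
#'   `flagged = TRUE`.
#' @export
estimate_diameter <- function(xs, ys, precision_nm = 10) {
  if (length(xs) < 1L) abort("cluster has no members")
  prec <- rep(precision_nm, length.out = length(xs))
  est <- fwhm_diameter(xs, ys, prec)
  structure(est$diameter_nm, flagged = est$flagged)
}

#' Assign receptor-channel localizations to segmented vesicles
#'
#' Each localization from the non-reference channels is assigned to the
#' nearest vesicle centroid if within `assign_radius`; ties go to the lowest
#' vesicle id. Per-channel counts are added to the vesicle table.
#'
#' @param vesicles A `vesicle_set` from [segment_vesicles()].
#' @param channel_tables Named list of localization tibbles, one per channel
#'   (e.g. `list(TCR = ..., CD40L = ...)`), registered to the reference frame.
#' @param assign_radius Assignment radius in nm (default 100).
#' @return The vesicle tibble with one `n_<channel>` count column per input
#'   channel and an `assignments` attribute (list of per-channel assignment
#'   vectors; 0 = unassigned).
#' @export
assign_channels <- function(vesicles, channel_tables, assign_radius = 100) {
  stopifnot(is.list(channel_tables), !is.null(names(channel_tables)))
  assignments <- list()
  for (ch in names(channel_tables)) {
    tb <- channel_tables[[ch]]
    counts <- integer(nrow(vesicles))
    asg <- integer(nrow(tb))
    if (nrow(tb) && nrow(vesicles) && assign_radius > 0) {
      d2 <- pdist2(tb$x_nm, tb$y_nm, vesicles$x_nm, vesicles$y_nm)
      # which.max of logical "is minimum" picks the lowest id on ties
      best <- apply(d2, 1L, function(z) which.max(z == min(z)))
      ok <- sqrt(d2[cbind(seq_len(nrow(tb)), best)]) <= assign_radius
      asg[ok] <- vesicles$id[best[ok]]
      tab <- table(factor(asg[ok], levels = vesicles$id))
      counts <- as.integer(tab)
    }
    vesicles[[paste0("n_", ch)]] <- counts
    assignments[[ch]] <- asg
  }
  attr(vesicles, "assignments") <- assignments
  vesicles
}

#' Classify per-vesicle protein positivity
#'
#' A channel is positive on a vesicle iff its assigned localization count is
#' at least `min_locs`. For the pairing (TCR, partner) each vesicle is
#' labelled `tcr-only`, `partner-only`, `double-positive`, or `negative`.
#'
#' @param vesicles Vesicle tibble with `n_<channel>` columns from
#'   [assign_channels()].
#' @param tcr,partner Channel names of the pairing (must match the count
#'   columns).
#' @param min_locs Positivity threshold (default 3 localizations).
#' @return The vesicle tibble with a `class` column.
#' @export
classify_positivity <- function(vesicles, tcr = "TCR", partner = "CD40L",
                                min_locs = 3) {
  ct <- vesicles[[paste0("n_", tcr)]]
  cp <- vesicles[[paste0("n_", partner)]]
  if (is.null(ct) || is.null(cp)) {
    abort("run assign_channels() for both pairing channels first")
  }
  pos_t <- ct >= min_locs; pos_p <- cp >= min_locs
  vesicles$class <- dplyr::case_when(
    pos_t & pos_p ~ "double-positive",
    pos_t ~ "tcr-only",
    pos_p ~ "partner-only",
    TRUE ~ "negative")
  vesicles
}

#' Positivity class percentages
#'
#' Percentages over vesicles positive for at least one channel of the
#' pairing; the three classes sum to exactly 100.
#'
#' @param vesicles Output of [classify_positivity()].
#' @return Tibble (class, n, percent).
#' @export
positivity_fractions <- function(vesicles) {
  pos <- vesicles[vesicles$class != "negative", , drop = FALSE]
  lv <- c("tcr-only", "partner-only", "double-positive")
  n <- as.integer(table(factor(pos$class, levels = lv)))
  tibble(class = lv, n = n,
         percent = if (sum(n)) 100 * n / sum(n) else rep(NA_real_, 3))
}

#' Detect receptor microclusters in a single channel
#'
#' The same density-based machinery as [segment_vesicles()], applied to a
#' receptor channel; sizes use the same FWHM metric as vesicle diameters.
#'
#' @inheritParams segment_vesicles
#' @param channel_table Corrected localization tibble of one receptor channel.
#' @return Tibble (id, x_nm, y_nm, n_locs, size_nm).
#' @export
detect_microclusters <- function(channel_table, eps = 50, min_pts = 5,
                                 precision_nm = NULL) {
  v <- segment_vesicles(channel_table, eps = eps, min_pts = min_pts,
                        precision_nm = precision_nm)
  tibble(id = v$id, x_nm = v$x_nm, y_nm = v$y_nm, n_locs = v$n_ref,
         size_nm = v$diameter_nm)
}

#' Per-cell vesicle statistics
#'
#' Maps each vesicle centroid to a cell footprint (containing footprint
#' first, else nearest footprint within `guard_nm`, else flagged unassigned)
#' and reports per-cell counts and median diameters. Cells with no vesicles
#' appear with count 0 and an undefined (NA) median.
#'
#' @param vesicles Vesicle tibble with centroid and `diameter_nm`.
#' @param cells Tibble (cell, cx_nm, cy_nm, radius_um), e.g. `scene$cells`.
#' @param guard_nm Guard radius beyond the footprint edge (default 2000 nm).
#' @return Tibble (cell, n_vesicles, median_diameter_nm) with an
#'   `n_unassigned` attribute.
#' @export
per_cell_stats <- function(vesicles, cells, guard_nm = 2000) {
  assert_cols(cells, c("cell", "cx_nm", "cy_nm", "radius_um"), "cells")
  assigned <- rep(NA_integer_, nrow(vesicles))
  if (nrow(vesicles)) {
    d <- sqrt(pdist2(vesicles$x_nm, vesicles$y_nm, cells$cx_nm, cells$cy_nm))
    edge <- sweep(d, 2L, cells$radius_um * 1000)  # distance beyond footprint
    nearest <- apply(edge, 1L, which.min)
    edge_min <- edge[cbind(seq_len(nrow(vesicles)), nearest)]
    assigned[edge_min <= guard_nm] <- cells$cell[nearest[edge_min <= guard_nm]]
  }
  vs <- vesicles
  vs$cell <- assigned
  stats <- summarise(group_by(filter(vs, !is.na(.data$cell)), .data$cell),
                     n_vesicles = dplyr::n(),
                     median_diameter_nm = median(.data$diameter_nm),
                     .groups = "drop")
  out <- left_join(cells["cell"], stats, by = "cell")
  out$n_vesicles[is.na(out$n_vesicles)] <- 0L
  attr(out, "n_unassigned") <- sum(is.na(assigned))
  out
}
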