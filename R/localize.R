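#' Detect candidate single-molecule peaks in a frame
#'
#' Local maxima above an intensity threshold, deduplicated within a 3x3
#' neighborhood (a pixel is kept only if it is the strict maximum of its
#' neighborhood; plateau ties keep the first pixel in column-major order).
#'
#' @param frame 2-D numeric matrix of non-negative pixel intensities.
#' @param threshold Minimum peak intensity.
#' @return A tibble with integer columns `row`, `col` and the peak `value`.
#' @export
detect_peaks <- function(frame, threshold) {
  if (!is.matrix(frame) || !is.numeric(frame)) abort("`frame` must be a numeric matrix")
  if (any(!is.finite(frame))) abort("`frame` contains non-finite pixels")
  ny <- nrow(frame); nx <- ncol(frame)
  if (ny < 3 || nx < 3) return(tibble(row = integer(), col = integer(),
                                      value = numeric()))
  inner <- frame[2:(ny - 1), 2:(nx - 1)]
  is_max <- inner >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- frame[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    # strict on "later" neighbors, non-strict on "earlier" ones, so exactly
    # one pixel of a flat plateau survives
    later <- dx > 0 || (dx == 0 && dy > 0)
    is_max <- is_max & (if (later) inner > nb else inner >= nb)
  }
  hit <- which(is_max, arr.ind = TRUE)
  tibble(row = hit[, 1] + 1L, col = hit[, 2] + 1L,
         value = frame[hit + 1L])
}

#' Fit a 2-D Gaussian to a candidate peak
#'
#' Least-squares fit of an integrated-intensity Gaussian plus constant
#' background in a square window around the candidate pixel. Positions are in
#' nm with the pixel-center convention that pixel (r, c) spans
#' ((c-1)..c, (r-1)..r) pixel units. The localization precision follows the
#' first-order Thompson rule `precision = sigma / sqrt(photons)`.
#'
#' @param frame 2-D numeric matrix.
#' @param row,col Candidate pixel (from [detect_peaks()]).
#' @param pixel_size_nm Camera pixel size in nm.
#' @param window Half-width of the fitting window in pixels; the window must
#'   lie fully inside the frame.
#' @return A one-row tibble (x_nm, y_nm, photons, sigma_nm, precision_nm,
#'   converged), or zero rows if the fit failed to converge.
#' @export
fit_gaussian <- function(frame, row, col, pixel_size_nm = 107, window = 5L) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (row - window < 1 || row + window > ny ||
      col - window < 1 || col + window > nx) {
    abort("fitting window out of frame bounds")
  }
  rows <- (row - window):(row + window)
  cols <- (col - window):(col + window)
  patch <- frame[rows, cols]
  xs <- cols - 0.5; ys <- rows - 0.5  # pixel centers, pixel units
  bg0 <- min(patch)
  amp0 <- sum(patch - bg0)
  model <- function(par) {
    px <- diff(stats::pnorm(c(cols - 1, cols[length(cols)]), par[1],
                            exp(par[4])))
    py <- diff(stats::pnorm(c(rows - 1, rows[length(rows)]), par[2],
                            exp(par[4])))
    exp(par[3]) * (py %o% px) + par[5]
  }
  obj <- function(par) sum((model(par) - patch)^2)
  init <- c(xs[window + 1], ys[window + 1], log(max(amp0, 1)), log(1.2), bg0)
  fit <- tryCatch(
    optim(init, obj, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  empty <- tibble(x_nm = numeric(), y_nm = numeric(), photons = numeric(),
                  sigma_nm = numeric(), precision_nm = numeric(),
                  converged = logical())
  if (is.null(fit)) return(empty)
  par <- fit$par
  photons <- exp(par[3]); sigma_nm <- exp(par[4]) * pixel_size_nm
  if (!all(is.finite(par)) || photons <= 0 ||
      par[1] < cols[1] - 1 || par[1] > cols[length(cols)] ||
      par[2] < rows[1] - 1 || par[2] > rows[length(rows)]) {
    return(empty)
  }
  tibble(x_nm = par[1] * pixel_size_nm, y_nm = par[2] * pixel_size_nm,
         photons = photons, sigma_nm = sigma_nm,
         precision_nm = sigma_nm / sqrt(photons),
         converged = fit$convergence == 0)
}

#' Localize an image stack
#'
#' Runs [detect_peaks()] and [fit_gaussian()] on every frame and collects the
#' results into a localization table. Non-convergent fits and candidates whose
#' fitting window falls outside the frame are dropped and counted.
#'
#' @param frames 3-D array (y, x, frame) or a `frame_sim`.
#' @param threshold Peak detection threshold (pixel intensity).
#' @param pixel_size_nm Camera pixel size in nm.
#' @param window Fitting window half-width in pixels.
#' @param channel Channel label for the output table.
#' @return A localization tibble (channel, frame, x_nm, y_nm, photons,
#'   sigma_nm, precision_nm), sorted by frame, with attributes
#'   `pixel_size_nm`, `n_frames` and `n_dropped`.
#' @export
localize_frames <- function(frames, threshold, pixel_size_nm = 107,
                            window = 5L, channel = "640") {
  if (inherits(frames, "frame_sim")) {
    pixel_size_nm <- frames$pixel_size_nm
    frames <- frames$frames
  }
  n_frames <- dim(frames)[3]
  out <- vector("list", n_frames)
  dropped <- 0L
  for (f in seq_len(n_frames)) {
    pk <- detect_peaks(frames[, , f], threshold)
    if (!nrow(pk)) next
    fits <- vector("list", nrow(pk))
    for (i in seq_len(nrow(pk))) {
      fit <- tryCatch(
        fit_gaussian(frames[, , f], pk$row[i], pk$col[i], pixel_size_nm,
                     window),
        error = function(e) NULL)
      if (is.null(fit) || !nrow(fit)) dropped <- dropped + 1L
      else fits[[i]] <- fit
    }
    got <- bind_rows(fits)
    if (nrow(got)) out[[f]] <- mutate(got, frame = f, channel = channel,
                                      .before = 1L)
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(channel = character(), frame = integer(), x_nm = numeric(),
                  y_nm = numeric(), photons = numeric(), sigma_nm = numeric(),
                  precision_nm = numeric(), converged = logical())
  }
  res <- arrange(res, .data$frame)
  attr(res, "pixel_size_nm") <- pixel_size_nm
  attr(res, "n_frames") <- n_frames
  attr(res, "n_dropped") <- dropped
  res
}

#' Photon-count quality filter
#'
#' Keeps exactly the localizations with `photons >= min_photons`, preserving
#' row order and table metadata. Idempotent and monotone in the threshold.
#'
#' @param table A localization tibble with a `photons` column.
#' @param min_photons Inclusive photon threshold (default 2000).
#' @return The filtered tibble.
#' @export
filter_photons <- function(table, min_photons = 2000) {
  assert_cols(table, "photons", "table")
  keep_attrs(table[table$photons >= min_photons, , drop = FALSE], table)
}

keep_attrs <- function(new, old) {
  for (a in c("pixel_size_nm", "n_frames")) {
    attr(new, a) <- attr(old, a)
  }
  new
}

#' Merge re-blinking localizations across consecutive frames
#'
#' Chains of localizations appearing in consecutive frames within `radius_px`
#' camera pixels of each other are replaced by a single localization at the
#' photon-weighted mean position, with summed photons and the first frame of
#' the chain. By default chains of any length are linked; `max_frames` caps a
#' chain (a cap of 5 reproduces a strict five-frame reading of the merging
#' rule).
#'
#' @param table A localization tibble sorted by frame (per channel).
#' @param radius_px Linking radius in camera pixels (default 1).
#' @param pixel_size_nm Camera pixel size in nm (defaults to the table's
#'   `pixel_size_nm` attribute).
#' @param max_frames Optional maximum chain length in frames (NULL = no cap).
#' @return The merged tibble with `n_merged` column giving chain lengths;
#'   never has more rows than the input; total photons of each chain are
#'   conserved.
#' @export
merge_consecutive <- function(table, radius_px = 1, pixel_size_nm = NULL,
                              max_frames = NULL) {
  assert_cols(table, c("frame", "x_nm", "y_nm", "photons"), "table")
  pixel_size_nm <- pixel_size_nm %||% attr(table, "pixel_size_nm") %||% 107
  radius_nm <- radius_px * pixel_size_nm
  if (!nrow(table)) return(table)
  split_ch <- if ("channel" %in% names(table)) table$channel else
    rep("all", nrow(table))
  pieces <- lapply(split(seq_len(nrow(table)), split_ch), function(idx) {
    merge_one_channel(table[idx, , drop = FALSE], radius_nm, max_frames)
  })
  out <- bind_rows(pieces)
  out <- arrange(out, .data$frame)
  keep_attrs(out, table)
}

merge_one_channel <- function(tb, radius_nm, max_frames) {
  tb <- arrange(tb, .data$frame)
  n <- nrow(tb)
  chain <- integer(n)       # chain id per row
  next_chain <- 0L
  # active chains from the previous frame: index by chain id
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_w <- numeric(0); act_frame <- integer(0); act_len <- integer(0)
  frames <- tb$frame
  ord <- order(frames)
  by_frame <- split(ord, frames[ord])
  for (fr_rows in by_frame) {
    fr <- frames[fr_rows[1]]
    live <- act_frame == fr - 1L &
      (if (is.null(max_frames)) TRUE else act_len < max_frames)
    cand <- which(live)
    used <- rep(FALSE, length(cand))
    for (i in fr_rows) {
      joined <- FALSE
      if (length(cand)) {
        d2 <- (act_x[cand] - tb$x_nm[i])^2 + (act_y[cand] - tb$y_nm[i])^2
        ok <- which(!used & d2 <= radius_nm^2)
        if (length(ok)) {
          j <- cand[ok[which.min(d2[ok])]]
          used[match(j, cand)] <- TRUE
          w <- tb$photons[i]
          act_x[j] <- (act_x[j] * act_w[j] + tb$x_nm[i] * w) / (act_w[j] + w)
          act_y[j] <- (act_y[j] * act_w[j] + tb$y_nm[i] * w) / (act_w[j] + w)
          act_w[j] <- act_w[j] + w
          act_frame[j] <- fr
          act_len[j] <- act_len[j] + 1L
          chain[i] <- act_id[j]
          joined <- TRUE
        }
      }
      if (!joined) {
        next_chain <- next_chain + 1L
        act_id <- c(act_id, next_chain)
        act_x <- c(act_x, tb$x_nm[i]); act_y <- c(act_y, tb$y_nm[i])
        act_w <- c(act_w, tb$photons[i])
        act_frame <- c(act_frame, fr); act_len <- c(act_len, 1L)
        chain[i] <- next_chain
      }
    }
  }
  grp <- split(seq_len(n), chain)
  rows <- lapply(grp, function(idx) {
    w <- tb$photons[idx]
    first <- idx[which.min(tb$frame[idx])]
    out <- tb[first, , drop = FALSE]
    out$x_nm <- sum(tb$x_nm[idx] * w) / sum(w)
    out$y_nm <- sum(tb$y_nm[idx] * w) / sum(w)
    out$photons <- sum(w)
    out$frame <- min(tb$frame[idx])
    if ("sigma_nm" %in% names(tb)) {
      out$sigma_nm <- sum(tb$sigma_nm[idx] * w) / sum(w)
      out$precision_nm <- out$sigma_nm / sqrt(out$photons)
    }
    out$n_merged <- length(idx)
    out
  })
  bind_rows(rows)
}

#' Render a localization table as a super-resolution image
#'
#' Each localization contributes a unit-mass 2-D Gaussian whose width is its
#' localization precision, so the image integral equals the number of
#' rendered localizations. Kernels are normalized on the discrete grid.
#'
#' @param table Localization tibble with `x_nm`, `y_nm` and `precision_nm`
#'   (all precisions > 0), or a `sigma_nm_render` override.
#' @param pixel_size_out_nm Output pixel size in nm (> 0).
#' @param extent_nm Optional c(xmin, xmax, ymin, ymax); defaults to the data
#'   bounding box padded by 5 render sigmas.
#' @param sigma_nm_render Optional single rendering sigma overriding
#'   per-localization precisions.
#' @return A `rendered_image`: list with `intensity` matrix (rows = y),
#'   `pixel_size_nm`, `origin_nm`.
#' @export
render_localizations <- function(table, pixel_size_out_nm,
                                 extent_nm = NULL, sigma_nm_render = NULL) {
  assert_cols(table, c("x_nm", "y_nm"), "table")
  if (pixel_size_out_nm <= 0) abort("`pixel_size_out_nm` must be > 0")
  sig <- sigma_nm_render %||% table$precision_nm
  if (is.null(sig)) abort("table needs a `precision_nm` column (or supply `sigma_nm_render`)")
  sig <- rep(sig, length.out = nrow(table))
  if (any(sig <= 0)) abort("all rendering precisions must be > 0")
  pad <- 5 * max(sig, 1)
  extent_nm <- extent_nm %||% c(min(table$x_nm) - pad, max(table$x_nm) + pad,
                                min(table$y_nm) - pad, max(table$y_nm) + pad)
  nx <- max(1L, ceiling((extent_nm[2] - extent_nm[1]) / pixel_size_out_nm))
  ny <- max(1L, ceiling((extent_nm[4] - extent_nm[3]) / pixel_size_out_nm))
  img <- matrix(0, nrow = ny, ncol = nx)
  for (i in seq_len(nrow(table))) {
    s <- sig[i]
    cx <- (table$x_nm[i] - extent_nm[1]) / pixel_size_out_nm
    cy <- (table$y_nm[i] - extent_nm[3]) / pixel_size_out_nm
    w <- ceiling(6 * s / pixel_size_out_nm)
    c0 <- max(1L, floor(cx) + 1L - w); c1 <- min(nx, floor(cx) + 1L + w)
    r0 <- max(1L, floor(cy) + 1L - w); r1 <- min(ny, floor(cy) + 1L + w)
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-((c(c0:c1) - 0.5) - cx)^2 * pixel_size_out_nm^2 / (2 * s^2))
    gy <- exp(-((c(r0:r1) - 0.5) - cy)^2 * pixel_size_out_nm^2 / (2 * s^2))
    ker <- gy %o% gx
    total <- sum(ker)
    if (total > 0) img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + ker / total
  }
  structure(list(intensity = img, pixel_size_nm = pixel_size_out_nm,
                 origin_nm = extent_nm[c(1, 3)]),
            class = "rendered_image")
}

#' Write / read localization tables as CSV
#'
#' The on-disk dialect has header `frame,x_nm,y_nm,photons,sigma_nm,channel`
#' (plus `precision_nm` when present). ThunderSTORM-style headers
#' (`"frame"`, `"x [nm]"`, `"y [nm]"`, `"intensity [photon]"`,
#' `"sigma [nm]"`) are accepted on read.
#'
#' @param table Localization tibble.
#' @param path CSV path.
#' @return `write_localizations` returns `path` invisibly; `read_localizations`
#'   a localization tibble.
#' @export
write_localizations <- function(table, path) {
  cols <- intersect(c("frame", "x_nm", "y_nm", "photons", "sigma_nm",
                      "precision_nm", "channel"), names(table))
  utils::write.csv(as.data.frame(table[, cols]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  alias <- c("x [nm]" = "x_nm", "y [nm]" = "y_nm",
             "intensity [photon]" = "photons", "sigma [nm]" = "sigma_nm",
             "uncertainty [nm]" = "precision_nm")
  hit <- names(df) %in% names(alias)
  names(df)[hit] <- alias[names(df)[hit]]
  out <- as_tibble(df)
  assert_cols(out, c("frame", "x_nm", "y_nm"), "localization file")
  arrange(out, .data$frame)
}
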