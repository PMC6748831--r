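#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rpois rlnorm rgeom rbinom median sd cor lm
#'   coef fft optim approx quantile setNames complete.cases
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a finite number in %s%s, %s]",
                  name, if (strict) "(" else "[", lower, upper))
  }
  invisible(x)
}

assert_cols <- function(data, cols, name = deparse(substitute(data))) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

#' Geometric mean of strictly positive values
#'
#' Geometric mean fluorescence intensity (GMFI) is defined over strictly
#' positive events only; zero or negative events are excluded and their count
#' attached as an attribute.
#'
#' @param x Numeric vector of intensities.
#' @return The geometric mean of the positive entries, with attribute
#'   `n_excluded` giving how many non-positive entries were dropped.
#' @export
#' @examples
#' gmfi(c(10, 100, 1000))
gmfi <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  n_excluded <- length(x) - length(pos)
  if (!length(pos)) abort("`x` has no strictly positive values; GMFI undefined")
  structure(exp(mean(log(pos))), n_excluded = n_excluded)
}

# Squared Euclidean distance matrix between two point sets (rows of a, b).
pdist2 <- function(ax, ay, bx, by) {
  outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
}

# For each point in A, distance to its nearest neighbour in B. Chunked so the
# full |A| x |B| matrix is never materialised for large inputs.
nn_dist <- function(ax, ay, bx, by, chunk = 2000L) {
  n <- length(ax)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- pdist2(ax[idx], ay[idx], bx, by)
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

# Ray-casting point-in-polygon test; poly is a matrix with columns x, y.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    xi <- poly[k, 1L]; yi <- poly[k, 2L]
    xj <- poly[j[k], 1L]; yj <- poly[j[k], 2L]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}
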