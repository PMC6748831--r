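#' Fold-change filter on a label-free abundance table
#'
#' Per-protein, per-experiment fold change `LFQ(plus) / LFQ(minus)` with the
#' missing-value rule of zero-inflated LFQ tables: detected in `plus` but
#' absent in `minus` gives an infinite (kept) enrichment; absent in `plus`
#' gives fold change 0 (kept only under two-sided filtering). By default a
#' protein is a candidate iff its enrichment is at least `threshold` in every
#' experiment; `direction = "absolute"` filters on `|log2 FC|` instead, and
#' `require_all_experiments = FALSE` keeps proteins passing in any
#' experiment.
#'
#' @param table Tidy abundance tibble: `protein`, `experiment`, `condition`
#'   ("plus"/"minus"), `intensity` (NA = missing).
#' @param threshold Linear fold-change threshold (default 3.35; candidates
#'   have fold change of at least the threshold).
#' @param require_all_experiments Require the criterion in every experiment
#'   (default TRUE).
#' @param direction `"enrichment"` (default) or `"absolute"` (two-sided on
#'   `|log2 FC|`).
#' @return Tibble of candidates (protein, plus per-experiment `fc_<k>`
#'   columns), with attributes `n_tested` and `n_excluded` (proteins missing
#'   everywhere).
#' @export
fold_change_filter <- function(table, threshold = 3.35,
                               require_all_experiments = TRUE,
                               direction = c("enrichment", "absolute")) {
  direction <- match.arg(direction)
  assert_cols(table, c("protein", "experiment", "condition", "intensity"),
              "table")
  if (!all(c("plus", "minus") %in% table$condition)) {
    abort("both conditions ('plus', 'minus') must be present")
  }
  if (threshold < 1) abort("`threshold` must be >= 1")
  wide <- tidyr::pivot_wider(
    summarise(group_by(table, .data$protein, .data$experiment,
                       .data$condition),
              intensity = mean(.data$intensity, na.rm = TRUE),
              .groups = "drop"),
    names_from = "condition", values_from = "intensity")
  wide$plus[is.nan(wide$plus)] <- NA_real_
  wide$minus[is.nan(wide$minus)] <- NA_real_
  all_missing <- summarise(group_by(wide, .data$protein),
                           gone = all(is.na(.data$plus) & is.na(.data$minus)),
                           .groups = "drop")
  excluded <- all_missing$protein[all_missing$gone]
  wide <- wide[!wide$protein %in% excluded, , drop = FALSE]
  wide$fc <- dplyr::case_when(
    !is.na(wide$plus) & !is.na(wide$minus) & wide$minus > 0 ~
      wide$plus / wide$minus,
    !is.na(wide$plus) & (is.na(wide$minus) | wide$minus == 0) ~ Inf,
    TRUE ~ 0)
  passes <- if (direction == "enrichment") wide$fc >= threshold else
    (wide$fc >= threshold | (wide$fc > 0 & wide$fc <= 1 / threshold) |
       wide$fc == 0)
  per_protein <- summarise(group_by(mutate(wide, pass = passes),
                                    .data$protein),
                           keep = if (require_all_experiments) all(.data$pass)
                                  else any(.data$pass),
                           .groups = "drop")
  kept <- per_protein$protein[per_protein$keep]
  fcs <- tidyr::pivot_wider(wide[wide$protein %in% kept,
                                 c("protein", "experiment", "fc")],
                            names_from = "experiment", values_from = "fc",
                            names_prefix = "fc_")
  out <- arrange(fcs, .data$protein)
  attr(out, "n_tested") <- dplyr::n_distinct(wide$protein)
  attr(out, "n_excluded") <- length(excluded)
  out
}

#' Markov clustering (MCL) of a confidence-weighted interaction network
#'
#' Standard MCL: the edge-confidence adjacency matrix (undirected, self-loops
#' added) is column-normalized into a stochastic matrix, then alternately
#' expanded (matrix square) and inflated (entrywise power `inflation`
#' followed by column renormalization), pruning entries below `prune`, until
#' the matrix is stable. Clusters are read off the limit matrix as connected
#' components of its support. Deterministic for a fixed input order.
#'
#' @param edges Tibble (`a`, `b`, `score`): undirected weighted edges,
#'   confidence scores in `(0, 1]`; self-loops are rejected.
#' @param inflation Inflation parameter (default 2.5).
#' @param max_iter Maximum iterations (default 200).
#' @param prune Entries below this are zeroed each iteration (default 1e-6).
#' @param tol Convergence tolerance on the max entry change (default 1e-8).
#' @return A tibble of class `module_partition` (`protein`, `module`) with
#'   attributes `inflation` and `n_iter`. Errors if not converged within
#'   `max_iter`.
#' @export
mcl <- function(edges, inflation = 2.5, max_iter = 200, prune = 1e-6,
                tol = 1e-8) {
  assert_cols(edges, c("a", "b", "score"), "edges")
  if (!nrow(edges)) abort("edge list is empty")
  if (any(edges$a == edges$b)) abort("self-loops are not allowed")
  if (any(edges$score <= 0)) abort("edge scores must be positive")
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
  for (k in seq_len(nrow(edges))) {
    M[ia[k], ib[k]] <- M[ia[k], ib[k]] + edges$score[k]
    M[ib[k], ia[k]] <- M[ib[k], ia[k]] + edges$score[k]
  }
  diag(M) <- pmax(apply(M, 2L, max), .Machine$double.eps)  # self-loops
  normalize <- function(m) sweep(m, 2L, colSums(m), "/")
  M <- normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                    # expansion
    M2 <- normalize(M2^inflation)    # inflation
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf("MCL did not converge within %d iterations (last delta %.3g)",
                  max_iter, delta))
  }
  support <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- tibble(protein = nodes, module = as.integer(comp))
  out <- arrange(out, .data$module, .data$protein)
  attr(out, "inflation") <- inflation
  attr(out, "n_iter") <- it
  class(out) <- c("module_partition", class(out))
  out
}

#' Filter and rank modules by size
#'
#' @param partition A `module_partition` from [mcl()].
#' @param min_size Minimum module size to report (default 3, mirroring
#'   "modules with three or more nodes").
#' @return Tibble (module, size, proteins list-column), sorted by size
#'   descending.
#' @export
module_filter <- function(partition, min_size = 3) {
  if (!nrow(partition)) {
    return(tibble(module = integer(), size = integer(), proteins = list()))
  }
  sizes <- summarise(group_by(partition, .data$module),
                     size = dplyr::n(),
                     proteins = list(.data$protein), .groups = "drop")
  out <- arrange(filter(sizes, .data$size >= min_size), dplyr::desc(.data$size))
  out
}

#' Read an edge list CSV (protein a, protein b, confidence score)
#'
#' Scores are clamped to the confidence window `[min_score, 0.999]`; edges
#' below `min_score` are dropped.
#'
#' @param path CSV with columns a, b, score.
#' @param min_score Minimum confidence score (default 0.4).
#' @return Edge tibble.
#' @export
read_edges <- function(path, min_score = 0.4) {
  df <- as_tibble(utils::read.csv(path))
  assert_cols(df, c("a", "b", "score"), "edge file")
  df <- df[df$score >= min_score & df$a != df$b, , drop = FALSE]
  df$score <- pmin(df$score, 0.999)
  df
}
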