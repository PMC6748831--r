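#' Parameters for a simulated label-free proteome
#'
#' Emulates a MaxQuant-style LFQ table from the BSLB enrichment experiment:
#' two conditions (`plus` = TCR-engaging ligand present, `minus` = control)
#' across independent experiments, with a subset of proteins truly enriched by
#' a configured linear fold change, log-normal measurement noise and explicit
#' missing values.
#'
#' @param n_proteins Number of proteins.
#' @param frac_enriched Fraction truly enriched in `plus`.
#' @param effect_fc True linear fold change of enriched proteins (>= 1).
#' @param n_experiments Independent experiments.
#' @param noise_sdlog Log-sd of multiplicative noise (0 = exact).
#' @param base_meanlog,base_sdlog Log-normal distribution of baseline LFQ
#'   intensities.
#' @param missing_rate Probability an individual intensity is missing (NA).
#' @return A validated parameter list.
#' @export
proteome_params <- function(n_proteins = 200, frac_enriched = 0.15,
                            effect_fc = 6, n_experiments = 2,
                            noise_sdlog = 0.2, base_meanlog = log(1e7),
                            base_sdlog = 1, missing_rate = 0) {
  stopifnot(n_proteins >= 1, frac_enriched >= 0, frac_enriched <= 1,
            effect_fc >= 1, n_experiments >= 1, noise_sdlog >= 0,
            missing_rate >= 0, missing_rate < 1)
  list(n_proteins = as.integer(n_proteins), frac_enriched = frac_enriched,
       effect_fc = effect_fc, n_experiments = as.integer(n_experiments),
       noise_sdlog = noise_sdlog, base_meanlog = base_meanlog,
       base_sdlog = base_sdlog, missing_rate = missing_rate)
}

#' Simulate an LFQ abundance table
#'
#' @param params A [proteome_params()] list.
#' @param seed Integer seed.
#' @return A tibble of class `sim_proteome` with columns `protein`,
#'   `experiment`, `condition` ("plus"/"minus") and `intensity` (NA encodes a
#'   missing value), plus a logical `truth` attribute flagging the truly
#'   enriched proteins.
#' @export
simulate_proteome <- function(params = proteome_params(), seed = 1) {
  p <- params
  with_seed(seed, {
    protein <- sprintf("P%04d", seq_len(p$n_proteins))
    enriched <- seq_len(p$n_proteins) <= round(p$frac_enriched * p$n_proteins)
    base <- rlnorm(p$n_proteins, p$base_meanlog, p$base_sdlog)
    grid <- expand.grid(protein = protein,
                        experiment = seq_len(p$n_experiments),
                        condition = c("plus", "minus"),
                        stringsAsFactors = FALSE)
    idx <- match(grid$protein, protein)
    mu <- base[idx] * ifelse(grid$condition == "plus" & enriched[idx],
                             p$effect_fc, 1)
    noise <- if (p$noise_sdlog > 0) {
      rlnorm(nrow(grid), -p$noise_sdlog^2 / 2, p$noise_sdlog)
    } else rep(1, nrow(grid))
    intensity <- mu * noise
    if (p$missing_rate > 0) {
      intensity[runif(nrow(grid)) < p$missing_rate] <- NA_real_
    }
    out <- as_tibble(grid)
    out$intensity <- intensity
    out <- arrange(out, .data$protein, .data$experiment, .data$condition)
    attr(out, "truth") <- tibble(protein = protein, enriched = enriched)
    class(out) <- c("sim_proteome", class(out))
    out
  })
}
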