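# Two-condition expression simulation with a targeted knockdown.

#' Simulate a control/knockdown expression matrix
#'
#' Per-gene log-normal baselines are independent of CpG-island association
#' (binding of a CxxC protein does not set expression); a designated "KDM2A"
#' transcript is scaled by `1 - knockdown_fraction` in the knockdown
#' condition. Replicate noise is multiplicative log-normal.
#'
#' @param genes Gene tibble (needs `gene`; an optional logical `expressed`
#'   column raises/lowers baselines, itself independent of island status).
#' @param n_replicates Replicates per condition (>= 2).
#' @param knockdown_fraction Fractional mRNA loss of the KDM2A transcript in
#'   the knockdown (default 0.6, i.e. an ~60% decrease).
#' @param noise_sd Replicate noise SD on the log2 scale (default 0.1).
#' @param seed Integer seed.
#' @return A tibble in long form: `gene`, `sample`, `condition`
#'   ("control"/"knockdown"), `expr` (linear scale). The knockdown target is
#'   the row `gene == "KDM2A"` (added if absent).
#' @export
simulate_expression <- function(genes, n_replicates = 3,
                                knockdown_fraction = 0.6,
                                noise_sd = 0.1, seed = 1) {
  if (knockdown_fraction < 0 || knockdown_fraction > 1) {
    abort("`knockdown_fraction` must be in [0, 1].")
  }
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  genes <- as_tibble(genes)
  ids <- genes$gene
  if (!"KDM2A" %in% ids) ids <- c(ids, "KDM2A")
  with_seed(seed, {
    if ("expressed" %in% names(genes)) {
      base_mu <- ifelse(c(genes$expressed, TRUE)[seq_along(ids)], 10, 5)
    } else {
      base_mu <- rep(8, length(ids))
    }
    base_log2 <- rnorm(length(ids), base_mu, 1.5)
    samples <- tibble(
      sample = c(paste0("ctl_", seq_len(n_replicates)),
                 paste0("kd_", seq_len(n_replicates))),
      condition = rep(c("control", "knockdown"), each = n_replicates)
    )
    out <- tidyr::crossing(tibble(gene = ids, base_log2 = base_log2), samples)
    kd_hit <- out$gene == "KDM2A" & out$condition == "knockdown"
    out$expr <- 2^(out$base_log2 + rnorm(nrow(out), 0, noise_sd)) *
      ifelse(kd_hit, 1 - knockdown_fraction, 1)
    select(out, "gene", "sample", "condition", "expr")
  })
}
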