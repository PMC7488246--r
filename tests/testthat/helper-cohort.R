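# Small synthetic cohorts used across the unit tests: 2 regions x 60 samples,
# 300 SNPs in blocks of 5, 3 causal SNPs per trait. Big enough for the
# pipeline to find the planted signal, small enough to keep the suite fast.
small_config <- function(seed = 1L, ...) {
  defaults <- list(n_samples_per_region = 60L,
                   regions = c("North", "South"),
                   n_snps = 300L, n_causal = 3L,
                   causal_effects = c(1.6, 1.0, 0.8),
                   hair_causal_effects = c(1.6, 1.0, 0.8),
                   ld_block_size = 5L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

small_cohort <- function(seed = 1L, ...) {
  simulate_cohort(small_config(seed = seed, ...))
}

# hand-built feature-score table for rule tests: all columns the scoring
# rules look at, with controllable values
toy_scores <- function(n, alphas = c(0.7, 0.5, 0.2, 0.1, 0.05, 0.01,
                                     0.005, 0.001, 0.0005)) {
  df <- data.frame(snp_id = sprintf("snp%03d", seq_len(n)),
                   f_rank = NA_integer_, mi_rank = NA_integer_,
                   stringsAsFactors = FALSE)
  for (a in alphas) df[[paste0("coef_", a)]] <- 0
  df
}
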