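# Small fixtures shared across test files. Everything is generated in code.

toy_cohort <- function(n = 30, p = 8, seed = 42, missing_rate = 0, name = "toy") {
  set.seed(seed)
  g <- matrix(rbinom(n * p, 2, 0.3), n, p)
  if (missing_rate > 0) g[runif(n * p) < missing_rate] <- NA
  y <- rep_len(c(0L, 1L), n)
  cohort_dataset(g, y, name = name,
                 rsids = sprintf("rs%06d", seq_len(p)),
                 sample_ids = sprintf("%s_s%03d", name, seq_len(n)))
}

# quick simulated multi-cohort fixture at desk scale
small_sim <- function(n_cohorts = 2, n = 200, p = 60, n_causal = 5,
                      beta = 1, shift_sd = 0.05, missing_rate = 0, seed = 1,
                      epistatic_pairs = NULL, effect_mult = rep(1, n_cohorts)) {
  simulate_cohorts(sim_config(
    n_cohorts = n_cohorts, n_samples_per_cohort = n, n_snps = p,
    n_causal = n_causal, effect_sizes = rep(beta, n_causal),
    epistatic_pairs = epistatic_pairs,
    cohort_maf_shift_sd = shift_sd,
    cohort_effect_multiplier = effect_mult,
    case_fraction_per_cohort = 0.5, missing_rate = missing_rate, seed = seed))
}

# a feature ranking built directly from an ordered rsid vector (rank 1 first)
manual_ranking <- function(rsids_in_order, method = "f_score") {
  n <- length(rsids_in_order)
  gwaskd:::new_feature_ranking(rsids_in_order, scores = rev(seq_len(n)),
                               method = method)
}
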