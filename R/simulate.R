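#' Simulation configuration for multi-cohort genotype data
#'
#' Describes a multi-cohort case/control GWAS generative model: a shared SNP
#' panel with per-cohort allele-frequency shifts, a set of causal SNPs with
#' additive log-odds effects, optional pairwise dosage-product (epistatic)
#' effects, cohort-specific case fractions and uniformly missing genotypes.
#'
#' Defaults emulate a five-cohort Alzheimer's-style setting: sample sizes and
#' case fractions follow the magnitudes of typical clinical genotyping cohorts
#' (240 to ~1500 samples, 57-70% cases), a 2000-SNP panel with 10 shared
#' causal SNPs of log-odds 0.5 per minor allele, moderate between-cohort
#' allele-frequency perturbation (sd 0.05) and 2% missing genotypes.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_samples_per_cohort Integer vector of per-cohort sample counts
#'   (recycled to `n_cohorts`).
#' @param n_snps SNP panel size.
#' @param n_causal Number of causal SNPs (chosen at random from the panel).
#' @param effect_sizes Additive per-allele log-odds effects, length `n_causal`.
#' @param epistatic_pairs Three-column matrix (or list of length-3 vectors):
#'   SNP index a, SNP index b, interaction log-odds coefficient applied to the
#'   dosage product.
#' @param base_maf_range Length-2 range in (0, 0.5] for the shared base minor
#'   allele frequency of each SNP.
#' @param cohort_maf_shift_sd Standard deviation of the per-cohort, per-SNP
#'   Gaussian allele-frequency shift. Shifted frequencies are clipped to
#'   [0.01, 0.99].
#' @param cohort_effect_multiplier Cross-cohort effect heterogeneity: either
#'   a length-`n_cohorts` vector multiplying all causal effects per cohort,
#'   or an `n_cohorts` x `n_causal` matrix of per-cohort, per-SNP
#'   multipliers. A zero entry makes that causal SNP inactive in that
#'   cohort, so shared and cohort-private causal SNPs can be planted (e.g.
#'   `rbind(c(1, 1, 1, 0), c(1, 1, 0, 1))` shares the first two SNPs and
#'   makes the last two private). Default 1 everywhere.
#' @param case_fraction_per_cohort Target case fractions in (0, 1),
#'   recycled to `n_cohorts`.
#' @param missing_rate Fraction in [0, 1) of genotype entries masked missing.
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohorts()]
#' @export
sim_config <- function(n_cohorts = 5,
                       n_samples_per_cohort = c(1462, 534, 1386, 240, 1310),
                       n_snps = 2000,
                       n_causal = 10,
                       effect_sizes = rep(0.5, n_causal),
                       epistatic_pairs = NULL,
                       base_maf_range = c(0.05, 0.5),
                       cohort_maf_shift_sd = 0.05,
                       cohort_effect_multiplier = rep(1, n_cohorts),
                       case_fraction_per_cohort = c(0.62, 0.67, 0.60, 0.70, 0.57),
                       missing_rate = 0.02,
                       seed = 1L) {
  n_cohorts <- as.integer(n_cohorts)
  assert_that(n_cohorts >= 1, "n_cohorts must be >= 1")
  n_samples_per_cohort <- as.integer(rep_len(n_samples_per_cohort, n_cohorts))
  assert_that(all(n_samples_per_cohort >= 1), "sample counts must be positive")
  n_snps <- as.integer(n_snps)
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  n_causal <- as.integer(n_causal)
  assert_that(n_causal >= 0, "n_causal must be non-negative")
  if (n_causal > n_snps) abort("n_causal must not exceed n_snps")
  assert_that(length(effect_sizes) == n_causal,
              "effect_sizes must have length n_causal")
  if (!is.null(epistatic_pairs)) {
    if (is.list(epistatic_pairs)) epistatic_pairs <- do.call(rbind, epistatic_pairs)
    epistatic_pairs <- matrix(as.numeric(epistatic_pairs), ncol = 3)
    idx <- epistatic_pairs[, 1:2]
    assert_that(all(idx >= 1 & idx <= n_snps & idx == floor(idx)),
                "epistatic pair indices must be SNP indices within the panel")
  }
  assert_that(length(base_maf_range) == 2 &&
                base_maf_range[1] > 0 && base_maf_range[2] <= 0.5 &&
                base_maf_range[1] <= base_maf_range[2],
              "base_maf_range must be an increasing pair in (0, 0.5]")
  assert_that(cohort_maf_shift_sd >= 0, "cohort_maf_shift_sd must be >= 0")
  case_fraction_per_cohort <- rep_len(case_fraction_per_cohort, n_cohorts)
  assert_that(all(case_fraction_per_cohort > 0 & case_fraction_per_cohort < 1),
              "case fractions must lie in (0, 1)")
  if (is.matrix(cohort_effect_multiplier)) {
    assert_that(nrow(cohort_effect_multiplier) == n_cohorts &&
                  ncol(cohort_effect_multiplier) == n_causal,
                "effect-multiplier matrix must be n_cohorts x n_causal")
  } else {
    cohort_effect_multiplier <- rep_len(cohort_effect_multiplier, n_cohorts)
  }
  assert_that(missing_rate >= 0 && missing_rate < 1,
              "missing_rate must lie in [0, 1)")

  structure(
    list(n_cohorts = n_cohorts,
         n_samples_per_cohort = n_samples_per_cohort,
         n_snps = n_snps,
         n_causal = n_causal,
         effect_sizes = as.numeric(effect_sizes),
         epistatic_pairs = epistatic_pairs,
         base_maf_range = as.numeric(base_maf_range),
         cohort_maf_shift_sd = as.numeric(cohort_maf_shift_sd),
         cohort_effect_multiplier = if (is.matrix(cohort_effect_multiplier)) {
           cohort_effect_multiplier
         } else as.numeric(cohort_effect_multiplier),
         case_fraction_per_cohort = as.numeric(case_fraction_per_cohort),
         missing_rate = as.numeric(missing_rate),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# solve intercept c so that mean(sigmoid(liability + c)) = target to 1e-6,
# by bisection on the sampled liabilities
solve_intercept <- function(liability, target, tol = 1e-6) {
  lo <- -50; hi <- 50
  f <- function(c) mean(sigmoid(liability + c)) - target
  if (f(lo) > 0 || f(hi) < 0) abort("case fraction unreachable by intercept shift")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol / 10) break
  }
  (lo + hi) / 2
}

#' Simulate multi-cohort case/control genotype datasets
#'
#' Generates one [cohort_dataset()] per cohort under the generative model of
#' [sim_config()]. For cohort `c` and SNP `j` the minor-allele frequency is
#' `clip(base_maf[j] + shift[c, j], 0.01, 0.99)` with `base_maf ~
#' U(base_maf_range)` and `shift ~ N(0, cohort_maf_shift_sd^2)`; dosages are
#' Binomial(2, maf). The disease liability is the additive causal score plus
#' any dosage-product interaction terms; an intercept is solved by bisection
#' so the expected case fraction matches the request to 1e-6, and case labels
#' follow Bernoulli(sigmoid(liability)) conditioned onto the requested total,
#' so realised case counts match the request within one sample. Missing
#' entries are masked uniformly at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohorts` (list of [cohort_dataset()]) and
#'   `truth`, a `ground_truth` list carrying `causal_indices`, `causal_rsids`,
#'   `effect_sizes`, `epistatic_pairs`, `per_cohort_mafs` (cohort x SNP
#'   matrix) and `rsids`.
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_cohorts = 2,
#'   n_samples_per_cohort = 100, n_snps = 50, n_causal = 3,
#'   effect_sizes = rep(1, 3), seed = 7))
#' sim$cohorts[[1]]
simulate_cohorts <- function(config) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  withr::local_seed(config$seed)

  p <- config$n_snps
  rsids <- sprintf("rs%06d", seq_len(p))
  base_maf <- runif(p, config$base_maf_range[1], config$base_maf_range[2])
  causal <- if (config$n_causal > 0) sort(sample.int(p, config$n_causal)) else integer(0)
  beta <- config$effect_sizes

  per_cohort_mafs <- matrix(NA_real_, config$n_cohorts, p)
  cohorts <- vector("list", config$n_cohorts)
  for (ci in seq_len(config$n_cohorts)) {
    n <- config$n_samples_per_cohort[ci]
    maf <- base_maf + rnorm(p, 0, config$cohort_maf_shift_sd)
    maf <- pmin(pmax(maf, 0.01), 0.99)
    per_cohort_mafs[ci, ] <- maf

    g <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), nrow = n, ncol = p)

    cem <- config$cohort_effect_multiplier
    mult <- if (is.matrix(cem)) cem[ci, ] else cem[ci]
    scalar_mult <- if (is.matrix(cem)) 1 else cem[ci]
    liability <- if (length(causal) > 0) {
      as.numeric(g[, causal, drop = FALSE] %*% (beta * mult))
    } else rep(0, n)
    if (!is.null(config$epistatic_pairs)) {
      ep <- config$epistatic_pairs
      for (r in seq_len(nrow(ep))) {
        liability <- liability +
          scalar_mult * ep[r, 3] * g[, ep[r, 1]] * g[, ep[r, 2]]
      }
    }

    target <- config$case_fraction_per_cohort[ci]
    m <- round(target * n)
    if (m <= 0 || m >= n) {
      abort(sprintf("case fraction %.3f yields a single-class cohort of size %d", target, n))
    }
    intercept <- solve_intercept(liability, target)
    prob <- sigmoid(liability + intercept)
    u <- runif(n)
    # Bernoulli draw conditioned onto the requested count: label the m
    # samples whose draw is most in favour of 'case'
    labels <- integer(n)
    labels[order(prob - u, decreasing = TRUE)[seq_len(m)]] <- 1L

    if (config$missing_rate > 0) {
      mask <- runif(n * p) < config$missing_rate
      g[mask] <- NA_real_
    }

    name <- sprintf("cohort%d", ci)
    cohorts[[ci]] <- cohort_dataset(
      g, labels, name = name, rsids = rsids,
      sample_ids = sprintf("%s_s%05d", name, seq_len(n)))
  }

  dimnames(per_cohort_mafs) <- list(sprintf("cohort%d", seq_len(config$n_cohorts)), rsids)
  truth <- structure(
    list(causal_indices = causal,
         causal_rsids = rsids[causal],
         effect_sizes = beta,
         cohort_effect_multiplier = config$cohort_effect_multiplier,
         epistatic_pairs = config$epistatic_pairs,
         per_cohort_mafs = per_cohort_mafs,
         rsids = rsids),
    class = "ground_truth")
  list(cohorts = cohorts, truth = truth)
}

#' Fraction of planted causal SNPs recovered by a ranking
#'
#' Measures how many of the simulator's planted causal SNPs appear in the
#' top-`k` of a feature ranking (or selected rsID set).
#'
#' @param truth `ground_truth` from [simulate_cohorts()].
#' @param ranking A [feature_ranking] tibble, a `common_feature_set`, or a
#'   character vector of rsIDs in rank order.
#' @param k Top-list size; must be at least the number of causal SNPs.
#' @return Recovered fraction in [0, 1].
#' @export
planted_recovery <- function(truth, ranking, k = length(truth$causal_rsids)) {
  causal <- truth$causal_rsids
  if (length(causal) == 0) abort("ground truth has no causal SNPs")
  top <- if (is.character(ranking)) {
    ranking
  } else if (inherits(ranking, "common_feature_set")) {
    ranking$rsids
  } else {
    dplyr::arrange(ranking, .data$rank)$rsid
  }
  assert_that(k >= length(causal), "k must be at least the number of causal SNPs")
  top <- head(top, k)
  length(intersect(top, causal)) / length(causal)
}
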