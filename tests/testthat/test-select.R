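make_counts_cohort <- function(case_counts, control_counts) {
  # build a single-SNP cohort realising the given 2 x 3 genotype table
  g <- c(rep(0:2, case_counts), rep(0:2, control_counts))
  y <- c(rep(1, sum(case_counts)), rep(0, sum(control_counts)))
  cohort_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "rs000001")), y)
}

test_that("trend statistic matches a hand-built hypergeometric oracle", {
  cases <- c(10, 20, 10); controls <- c(20, 15, 5)
  d <- make_counts_cohort(cases, controls)
  rk <- association_test(d)

  # oracle: U = sum w (observed case count - expected), w = (0, 1, 2), with
  # the multivariate-hypergeometric variance, written out term by term
  w <- c(0, 1, 2)
  n_i <- cases + controls
  N <- sum(n_i); R <- sum(cases)
  U <- sum(w * cases) - R * sum(w * n_i) / N
  V <- R * (N - R) / (N^2 * (N - 1)) * (N * sum(w^2 * n_i) - sum(w * n_i)^2)
  z <- U / sqrt(V)
  expect_equal(rk$statistic, z, tolerance = 1e-10)
  expect_equal(rk$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)

  # independent library oracle: prop.trend.test divides by N where the
  # hypergeometric variance divides by N - 1, so chi-square = z^2 * N/(N - 1)
  pt <- prop.trend.test(cases, n_i, score = w)
  expect_equal(rk$statistic^2 * N / (N - 1), unname(pt$statistic),
               tolerance = 1e-8)
})

test_that("constant SNPs get p = 1 and the scan needs two classes", {
  g <- cbind(rs000001 = rep(1, 20), rs000002 = rbinom(20, 2, 0.4))
  d <- cohort_dataset(g, rep_len(c(0, 1), 20))
  rk <- association_test(d)
  expect_equal(rk$p_value[rk$rsid == "rs000001"], 1)
  expect_equal(rk$score[rk$rsid == "rs000001"], 0)

  one_class <- cohort_dataset(g, rep(1L, 20))
  expect_error(association_test(one_class), "both classes")
})

test_that("permutation null reproduces the analytic trend p-value", {
  set.seed(31)
  g <- rbinom(120, 2, 0.35)
  y <- rbinom(120, 1, 0.5)
  d <- cohort_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "rs000001")), y)
  rk <- association_test(d)
  obs <- abs(rk$statistic)
  perm <- vapply(1:2000, function(i) {
    dp <- cohort_dataset(d$genotypes, sample(y))
    abs(association_test(dp)$statistic)
  }, numeric(1))
  p_emp <- mean(perm >= obs - 1e-12)
  mc_err <- 3 * sqrt(rk$p_value * (1 - rk$p_value) / 2000)
  expect_lt(abs(p_emp - rk$p_value), mc_err + 0.02)
})

test_that("F-score equals the squared pooled-variance t statistic", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    y <- rep_len(c(0, 1), n)
    x <- rbinom(n, 2, runif(1, 0.1, 0.5)) + rnorm(n, 0, 1e-6)
    d <- cohort_dataset(matrix(pmin(pmax(x, 0), 2), ncol = 1,
                               dimnames = list(NULL, "rs000001")), y)
    f <- f_score(d)$score
    tt <- t.test(d$genotypes[y == 1, 1], d$genotypes[y == 0, 1],
                 var.equal = TRUE)
    expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-8)
  }
})

test_that("degenerate F-score columns are handled rank-safely", {
  g <- cbind(rs000001 = rep(1, 6),                  # constant -> 0
             rs000002 = c(0, 0, 0, 2, 2, 2),        # perfect separation
             rs000003 = c(0, 1, 2, 0, 1, 1))
  d <- cohort_dataset(g, c(0, 0, 0, 1, 1, 1))
  rk <- f_score(d)
  expect_equal(rk$score[rk$rsid == "rs000001"], 0)
  expect_equal(rk$rank[rk$rsid == "rs000002"], 1L)
  expect_true(all(is.finite(rk$score)))

  tiny <- cohort_dataset(g[c(1, 4, 5), ], c(0, 1, 1))
  expect_error(f_score(tiny), "at least 2")
})

test_that("mutual information matches direct joint-table summation", {
  # independence: joint table is the exact product of its margins
  ind <- make_counts_cohort(c(8, 12, 4) * 2, c(8, 12, 4))
  expect_equal(mutual_information(ind)$score, 0, tolerance = 1e-12)

  # perfect determination of a balanced label: MI = ln 2
  det <- cohort_dataset(matrix(c(rep(0, 10), rep(2, 10)), ncol = 1,
                               dimnames = list(NULL, "rs000001")),
                        rep(c(0, 1), each = 10))
  expect_equal(mutual_information(det)$score, log(2), tolerance = 1e-12)

  # random table vs direct-sum oracle
  set.seed(5)
  for (i in 1:10) {
    cases <- rmultinom(1, 40, c(0.3, 0.5, 0.2))[, 1]
    controls <- rmultinom(1, 35, c(0.5, 0.3, 0.2))[, 1]
    d <- make_counts_cohort(cases, controls)
    mi <- mutual_information(d)$score
    joint <- rbind(controls, cases) / (sum(cases) + sum(controls))
    px <- colSums(joint); py <- rowSums(joint)
    direct <- 0
    for (a in 1:2) for (b in 1:3) {
      if (joint[a, b] > 0) {
        direct <- direct + joint[a, b] * log(joint[a, b] / (py[a] * px[b]))
      }
    }
    expect_equal(mi, unname(direct), tolerance = 1e-12)
  }
})

test_that("rankings are invariant to sample order", {
  d <- toy_cohort(n = 40, p = 10, seed = 23)
  perm <- sample(seq_len(40))
  dp <- cohort_dataset(d$genotypes[perm, ], d$labels[perm],
                       rsids = d$rsids, sample_ids = d$sample_ids[perm])
  for (fn in list(f_score, mutual_information, association_test)) {
    a <- fn(d); b <- fn(dp)
    expect_equal(a$score, b$score)
    expect_identical(a$rsid, b$rsid)
  }
})

test_that("common top selection intersects per-cohort top lists", {
  rs <- sprintf("s%02d", 1:20)
  # identical rankings: top 5 of either
  r1 <- manual_ranking(rs)
  out <- select_common_top(list(a = r1, b = r1), m_per_cohort = 10, k = 5)
  expect_identical(out$rsids, rs[1:5])

  # offset top lists: candidates bounded by the intersection
  r2 <- manual_ranking(c(rs[6:15], rs[c(1:5, 16:20)]))
  out2 <- select_common_top(list(a = r1, b = r2), m_per_cohort = 10, k = 5)
  expect_true(all(out2$rsids %in% rs[6:10]))
  expect_equal(out2$shortfall, 0L)

  # intersection smaller than k: shortfall flagged
  expect_warning(
    short <- select_common_top(list(a = r1, b = r2), m_per_cohort = 10, k = 8),
    "fewer")
  expect_equal(short$shortfall, 3L)
  expect_equal(length(short$rsids), 5L)

  # selected set is a subset of every cohort's top-m list
  set.seed(41)
  rks <- lapply(1:3, function(i) manual_ranking(sample(rs)))
  names(rks) <- c("a", "b", "c")
  res <- suppressWarnings(select_common_top(rks, m_per_cohort = 15, k = 5))
  for (r in rks) {
    expect_true(all(res$rsids %in% head(dplyr::arrange(r, rank)$rsid, 15)))
  }

  expect_error(select_common_top(list(), 10, 5), "non-empty")
  expect_error(select_common_top(list(a = r1), m_per_cohort = 5, k = 10), "exceed")
})

test_that("overlap curves obey the identity, pigeonhole and random baselines", {
  rs <- sprintf("s%03d", 1:100)
  r <- manual_ranking(rs)
  same <- overlap_curve(r, r, thresholds = c(1, 10, 50, 100))
  expect_equal(same$overlap, c(1L, 10L, 50L, 100L))

  rev_r <- manual_ranking(rev(rs))
  opp <- overlap_curve(r, rev_r, thresholds = c(10, 40, 60, 90))
  expect_equal(opp$overlap, pmax(0L, 2L * c(10L, 40L, 60L, 90L) - 100L))

  expect_warning(capped <- overlap_curve(r, rev_r, thresholds = 150), "capped")
  expect_equal(capped$overlap, 100L)

  # monotone non-decreasing
  set.seed(13)
  ra <- manual_ranking(sample(rs)); rb <- manual_ranking(sample(rs))
  curve <- overlap_curve(ra, rb, thresholds = seq(5, 100, by = 5))
  expect_true(all(diff(curve$overlap) >= 0))
})

test_that("random independent rankings overlap at the hypergeometric rate", {
  rs <- sprintf("s%04d", 1:1000)
  set.seed(3)
  overlaps <- vapply(1:200, function(i) {
    a <- manual_ranking(sample(rs)); b <- manual_ranking(sample(rs))
    overlap_curve(a, b, 100)$overlap
  }, integer(1))
  # E|top-100 \cap top-100| = t^2 / n = 10; sd ~ 3, so 200-seed mean +- 1
  expect_lt(abs(mean(overlaps) - 10), 1)
})

test_that("null association p-values are approximately uniform", {
  cfg <- sim_config(n_cohorts = 1, n_samples_per_cohort = 200, n_snps = 5000,
                    n_causal = 0, effect_sizes = numeric(0),
                    case_fraction_per_cohort = 0.5, missing_rate = 0, seed = 19)
  sim <- simulate_cohorts(cfg)
  p <- association_test(sim$cohorts[[1]])$p_value
  # genotype tables make the p-values discrete, so bound the KS distance of
  # the empirical CDF from uniform rather than testing against a continuous
  # null; 0.05 catches any systematic miscalibration at n = 5000 SNPs
  grid <- seq(0.05, 0.95, by = 0.05)
  ks_dist <- max(abs(vapply(grid, function(q) mean(p <= q), numeric(1)) - grid))
  expect_lt(ks_dist, 0.05)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})
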