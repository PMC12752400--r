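new_feature_ranking <- function(rsids, scores, method, ascending = FALSE,
                                extra = NULL) {
  ord_scores <- if (ascending) scores else -scores
  ranks <- dplyr::dense_rank(ord_scores)
  out <- tibble(rsid = rsids, score = scores, rank = ranks)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out <- dplyr::arrange(out, .data$rank, .data$rsid)
  class(out) <- c("feature_ranking", class(out))
  attr(out, "method") <- method
  out
}

# p x 3 matrix of per-SNP genotype-class counts over a row subset
genotype_counts <- function(g, rows = NULL) {
  if (!is.null(rows)) g <- g[rows, , drop = FALSE]
  matrix(vapply(0:2, function(v) colSums(g == v), numeric(ncol(g))),
         ncol = 3)
}

check_imputed <- function(dataset) {
  if (anyNA(dataset$genotypes)) {
    abort("dataset contains missing genotypes; impute first (see impute_missing)")
  }
}

check_two_classes <- function(dataset, min_per_class = 1) {
  tab <- table(factor(dataset$labels, levels = c(0, 1)))
  if (any(tab < min_per_class)) {
    abort(sprintf("both classes need at least %d sample(s)", min_per_class))
  }
}

#' Per-SNP association scan (Cochran-Armitage trend test)
#'
#' Scores every SNP with the additive (Cochran-Armitage) trend test on the
#' 2 x 3 genotype-count table, the standard GWAS single-variant test. Real
#' valued (imputed) dosages are rounded to the nearest genotype class for
#' counting. Returns two-sided p-values and `-log10(p)`; SNPs with no dosage
#' variation get p = 1.
#'
#' @param dataset An imputed [cohort_dataset()] with both classes present.
#' @return A `feature_ranking` tibble (`method = "association_p"`) with
#'   columns `rsid`, `score` (= `-log10(p)`), `rank`, `p_value`, `statistic`
#'   (the signed trend z statistic). Rank 1 is the smallest p-value.
#' @export
#' @examples
#' sim <- simulate_cohorts(sim_config(n_cohorts = 1, n_samples_per_cohort = 300,
#'   n_snps = 40, n_causal = 2, effect_sizes = c(1.5, 1.5), missing_rate = 0,
#'   seed = 1))
#' head(association_test(sim$cohorts[[1]]), 3)
association_test <- function(dataset) {
  check_imputed(dataset)
  check_two_classes(dataset)
  g <- round(dataset$genotypes)
  g[g < 0] <- 0; g[g > 2] <- 2
  y <- dataset$labels
  n <- length(y)
  R <- sum(y)                      # cases
  w <- c(0, 1, 2)

  # per-SNP genotype counts, overall and among cases
  counts <- genotype_counts(g)
  case_counts <- genotype_counts(g, rows = which(y == 1))

  sw <- counts %*% w               # sum_i w_i n_i
  sw2 <- counts %*% w^2
  U <- case_counts %*% w - R * sw / n
  # variance of sum_i w_i s_i under the multivariate hypergeometric null
  V <- R * (n - R) * (n * sw2 - sw^2) / (n^2 * (n - 1))
  z <- ifelse(V > 0, U / sqrt(V), 0)
  p <- ifelse(V > 0, 2 * pnorm(-abs(z)), 1)
  new_feature_ranking(dataset$rsids, -log10(p), "association_p",
                      ascending = FALSE,
                      extra = tibble(p_value = as.numeric(p),
                                     statistic = as.numeric(z)))
}

#' Per-SNP F-score (one-way ANOVA F statistic)
#'
#' Scores each SNP by the ratio of between-class to within-class variance of
#' its dosage: the one-way ANOVA F statistic across the case/control groups.
#' SNPs with zero within-group and zero between-group variance score 0;
#' perfect separation (zero within-group variance with distinct group means)
#' is rank-safe: such SNPs receive the maximum finite score plus one.
#'
#' @param dataset An imputed [cohort_dataset()]; each class needs >= 2
#'   samples.
#' @return A `feature_ranking` tibble (`method = "f_score"`).
#' @export
f_score <- function(dataset) {
  check_imputed(dataset)
  check_two_classes(dataset, min_per_class = 2)
  g <- dataset$genotypes
  y <- dataset$labels
  n <- length(y)
  n1 <- sum(y == 1); n0 <- n - n1

  m1 <- colMeans(g[y == 1, , drop = FALSE])
  m0 <- colMeans(g[y == 0, , drop = FALSE])
  m <- colMeans(g)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((t(t(g[y == 1, , drop = FALSE]) - m1))^2) +
    colSums((t(t(g[y == 0, , drop = FALSE]) - m0))^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  if (any(is.infinite(f))) {
    finite_max <- if (any(is.finite(f))) max(f[is.finite(f)]) else 0
    f[is.infinite(f)] <- finite_max + 1
  }
  new_feature_ranking(dataset$rsids, as.numeric(f), "f_score")
}

#' Per-SNP mutual information with the phenotype
#'
#' Plug-in discrete mutual information (in nats) between the 3-level genotype
#' dosage and the binary label. Real-valued (imputed) dosages are binned to
#' the nearest of \{0, 1, 2\}. Constant SNPs score 0.
#'
#' @param dataset An imputed [cohort_dataset()] with both classes present.
#' @param n_bins Number of dosage bins (fixed at 3 genotype classes;
#'   retained for interface compatibility).
#' @return A `feature_ranking` tibble (`method = "mutual_information"`).
#' @export
mutual_information <- function(dataset, n_bins = 3) {
  check_imputed(dataset)
  check_two_classes(dataset)
  g <- round(dataset$genotypes)
  g[g < 0] <- 0; g[g > 2] <- 2
  y <- dataset$labels
  n <- length(y)

  counts1 <- genotype_counts(g, rows = which(y == 1))
  counts0 <- genotype_counts(g, rows = which(y == 0))
  joint <- cbind(counts0, counts1) / n      # p x 6: (x = 0..2) x (y = 0, 1)
  px <- counts0 / n + counts1 / n           # p x 3
  py1 <- sum(y) / n
  pyv <- c(rep(1 - py1, 3), rep(py1, 3))
  pxv <- cbind(px, px)
  term <- joint * log(joint / (pxv * rep(pyv, each = nrow(joint))))
  term[joint == 0] <- 0
  mi <- pmax(rowSums(term), 0)              # clamp tiny negative round-off
  new_feature_ranking(dataset$rsids, as.numeric(mi), "mutual_information")
}

#' Cross-cohort consistent top-SNP selection
#'
#' Intersects the per-cohort top-`m` rsID lists, ranks the surviving SNPs by
#' the mean of their per-cohort ranks, and keeps the best `k` (ties broken
#' lexicographically by rsID). An SNP highly ranked in some cohorts but
#' outside the top-`m` of any other is excluded. If fewer than `k` SNPs
#' survive the intersection, all survivors are returned and the shortfall is
#' flagged with a warning and the `shortfall` attribute.
#'
#' @param rankings Named list of `feature_ranking` tibbles, one per cohort,
#'   over a harmonised rsID universe.
#' @param m_per_cohort Per-cohort top-list size fed into the intersection.
#' @param k Final selected-set size (`k <= m_per_cohort`).
#' @return A `common_feature_set`: a list with `rsids` (ordered, best
#'   first), `per_cohort_ranks` (tibble), `aggregate_rank`, `m_per_cohort`,
#'   `k` and `shortfall`.
#' @export
select_common_top <- function(rankings, m_per_cohort, k) {
  assert_that(length(rankings) >= 1, "rankings must be a non-empty list")
  assert_that(k <= m_per_cohort, "k must not exceed m_per_cohort")
  universe <- rankings[[1]]$rsid
  for (r in rankings) {
    assert_that(setequal(r$rsid, universe),
                "rankings must share a harmonised rsID universe")
  }
  if (is.null(names(rankings))) names(rankings) <- sprintf("cohort%d", seq_along(rankings))

  top_sets <- lapply(rankings, function(r) {
    head(dplyr::arrange(r, .data$rank, .data$rsid)$rsid, m_per_cohort)
  })
  candidates <- Reduce(intersect, top_sets)

  rank_tbl <- purrr::imap(rankings, function(r, nm) {
    tibble(rsid = r$rsid, !!nm := r$rank)
  })
  rank_tbl <- purrr::reduce(rank_tbl, dplyr::inner_join, by = "rsid")
  cand_tbl <- dplyr::filter(rank_tbl, .data$rsid %in% candidates)
  agg <- rowMeans(as.matrix(cand_tbl[, -1, drop = FALSE]))
  cand_tbl <- dplyr::mutate(cand_tbl, aggregate_rank = agg)
  cand_tbl <- dplyr::arrange(cand_tbl, .data$aggregate_rank, .data$rsid)

  shortfall <- max(0L, k - nrow(cand_tbl))
  if (shortfall > 0) {
    warn(sprintf("cross-cohort intersection holds %d SNP(s), fewer than k = %d",
                 nrow(cand_tbl), k))
  }
  kept <- head(cand_tbl, k)
  structure(
    list(rsids = kept$rsid,
         per_cohort_ranks = kept,
         aggregate_rank = kept$aggregate_rank,
         m_per_cohort = m_per_cohort,
         k = k,
         shortfall = shortfall),
    class = "common_feature_set")
}

#' @export
print.common_feature_set <- function(x, ...) {
  cat(sprintf("<common_feature_set: %d SNPs (k = %d, m = %d per cohort)%s>\n",
              length(x$rsids), x$k, x$m_per_cohort,
              if (x$shortfall > 0) sprintf("; shortfall %d", x$shortfall) else ""))
  print(head(x$per_cohort_ranks, 10))
  invisible(x)
}

#' Top-list overlap curve between two rankings
#'
#' For each threshold `t`, counts the SNPs shared by the two rankings'
#' top-`t` lists. Used to compare selection methods (e.g. F-score vs mutual
#' information) across list sizes.
#'
#' @param ranking_a,ranking_b `feature_ranking` tibbles over the same rsID
#'   universe.
#' @param thresholds Integer vector of top-list sizes; values beyond the
#'   universe size are capped with a warning.
#' @return A tibble of class `overlap_curve` with columns `threshold` and
#'   `overlap`, non-decreasing in `threshold`.
#' @export
overlap_curve <- function(ranking_a, ranking_b, thresholds) {
  assert_that(setequal(ranking_a$rsid, ranking_b$rsid),
              "rankings must share an rsID universe")
  universe <- nrow(ranking_a)
  if (any(thresholds > universe)) {
    warn(sprintf("threshold(s) beyond the %d-SNP universe capped", universe))
    thresholds <- pmin(thresholds, universe)
  }
  a <- dplyr::arrange(ranking_a, .data$rank, .data$rsid)$rsid
  b <- dplyr::arrange(ranking_b, .data$rank, .data$rsid)$rsid
  out <- tibble(
    threshold = as.integer(thresholds),
    overlap = vapply(thresholds, function(t) {
      length(intersect(head(a, t), head(b, t)))
    }, integer(1)))
  class(out) <- c("overlap_curve", class(out))
  out
}

#' Write a feature ranking or common feature set as TSV
#'
#' @param x A `feature_ranking` or `common_feature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  df <- if (inherits(x, "common_feature_set")) x$per_cohort_ranks else x
  utils::write.table(as.data.frame(df), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
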