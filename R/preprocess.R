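#' Harmonise cohorts onto their shared rsID universe
#'
#' Restricts every cohort to the sorted intersection of all cohorts' rsID
#' sets, so downstream rankings and models see an identical SNP order.
#' Sample rows are untouched. Idempotent.
#'
#' @param datasets List of two or more [cohort_dataset()] objects.
#' @return List of cohorts with identical `rsids`.
#' @export
harmonise_cohorts <- function(datasets) {
  assert_that(length(datasets) >= 2, "need at least two cohorts to harmonise")
  shared <- Reduce(intersect, lapply(datasets, `[[`, "rsids"))
  if (length(shared) == 0) abort("cohorts share no rsIDs")
  shared <- sort(shared)
  lapply(datasets, function(d) cohort_subset(d, cols = match(shared, d$rsids)))
}

# per-SNP means of observed dosages (imputation statistics)
snp_means <- function(dataset) {
  colMeans(dataset$genotypes, na.rm = TRUE)
}

#' Impute missing genotypes
#'
#' `mean` fills each missing cell with the per-SNP mean of observed dosages
#' (real-valued fills are kept). `nearest_neighbour` fills with the mean
#' dosage of the `k_neighbours` samples closest in Euclidean distance over
#' mutually observed SNPs (distance rescaled to the full SNP dimension so
#' pairs sharing few SNPs are not favoured). SNPs with no observed value are
#' dropped with a warning.
#'
#' When imputation is applied inside a train/test split, pass the training
#' set's [snp_means] via `stats` so test-set fills use training statistics
#' only (no leakage); this applies to the mean method.
#'
#' @param dataset A [cohort_dataset()].
#' @param method `"mean"` or `"nearest_neighbour"`.
#' @param k_neighbours Neighbour count for the nearest-neighbour method.
#' @param stats Optional named per-SNP fill means (from a training split).
#' @return A [cohort_dataset()] with no missing entries.
#' @export
impute_missing <- function(dataset, method = c("mean", "nearest_neighbour"),
                           k_neighbours = 5, stats = NULL) {
  method <- match.arg(method)
  g <- dataset$genotypes
  all_missing <- colSums(!is.na(g)) == 0
  if (any(all_missing) && is.null(stats)) {
    warn(sprintf("dropping %d SNP(s) with no observed genotypes: %s",
                 sum(all_missing),
                 paste(head(dataset$rsids[all_missing], 5), collapse = ", ")))
    dataset <- cohort_subset(dataset, cols = which(!all_missing))
    g <- dataset$genotypes
  }
  if (!anyNA(g)) return(dataset)

  if (method == "mean") {
    fill <- if (is.null(stats)) colMeans(g, na.rm = TRUE) else stats[dataset$rsids]
    if (anyNA(fill)) abort("fill statistics missing for some SNPs")
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- fill[idx[, 2]]
  } else {
    n <- nrow(g)
    if (k_neighbours >= n) abort("k_neighbours must be smaller than the sample count")
    p <- ncol(g)
    # pairwise distance over mutually observed SNPs, rescaled to p dimensions
    obs <- !is.na(g)
    g0 <- g; g0[!obs] <- 0
    sq <- g0^2
    cross <- tcrossprod(g0)
    sums_a <- sq %*% t(obs)           # sum_j a_j^2 over shared
    shared <- tcrossprod(obs * 1)
    d2 <- sums_a + t(sums_a) - 2 * cross
    d2 <- ifelse(shared > 0, p * d2 / shared, Inf)
    diag(d2) <- Inf
    miss_idx <- which(is.na(g), arr.ind = TRUE)
    for (r in seq_len(nrow(miss_idx))) {
      i <- miss_idx[r, 1]; j <- miss_idx[r, 2]
      cand <- which(obs[, j])
      if (length(cand) == 0) next
      ord <- cand[order(d2[i, cand])]
      nb <- head(ord, k_neighbours)
      g[i, j] <- mean(g[nb, j])
    }
    # any cell still missing (no observed neighbour) falls back to SNP mean
    if (anyNA(g)) {
      fill <- colMeans(g, na.rm = TRUE)
      idx <- which(is.na(g), arr.ind = TRUE)
      g[idx] <- fill[idx[, 2]]
    }
  }
  cohort_dataset(g, dataset$labels, name = dataset$name,
                 rsids = dataset$rsids, sample_ids = dataset$sample_ids)
}

#' Balance classes by oversampling then undersampling
#'
#' Two-stage balancing: the minority class is oversampled with replacement up
#' to `ratio` times the majority count (original minority samples are always
#' kept), then the majority class is undersampled without replacement down to
#' the new minority count. Final class counts are equal; every output row is
#' a copy of some input row. Deterministic given `seed`.
#'
#' @param dataset A [cohort_dataset()] containing both classes.
#' @param ratio Oversampling target as a fraction of the majority count.
#' @param seed Integer seed.
#' @return A balanced [cohort_dataset()].
#' @export
balance_classes <- function(dataset, ratio = 0.8, seed = 1L) {
  y <- dataset$labels
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) abort("both classes must be present to balance")
  withr::local_seed(seed)
  minority <- as.integer(names(tab)[which.min(tab)])
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  target <- round(ratio * length(maj_idx))
  new_min <- if (length(min_idx) >= target) {
    min_idx
  } else {
    extra <- min_idx[sample.int(length(min_idx), target - length(min_idx),
                                replace = TRUE)]
    c(min_idx, extra)
  }
  new_maj <- if (length(maj_idx) > length(new_min)) {
    maj_idx[sample.int(length(maj_idx), length(new_min))]
  } else {
    maj_idx
  }
  rows <- sort(c(new_min, new_maj))
  g <- dataset$genotypes[rows, , drop = FALSE]
  ids <- make.unique(dataset$sample_ids[rows], sep = "_dup")
  cohort_dataset(g, y[rows], name = dataset$name,
                 rsids = dataset$rsids, sample_ids = ids)
}

# stratified index split: per class, round(fraction * n_class) test samples
stratified_test_indices <- function(y, test_fraction, seed) {
  withr::local_seed(seed)
  test <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_test <- round(test_fraction * length(idx))
    n_test <- max(1L, min(length(idx) - 1L, n_test))
    test <- c(test, idx[sample.int(length(idx), n_test)])
  }
  sort(test)
}

#' Stratified train/test split
#'
#' Splits a cohort into disjoint train and test parts, preserving the class
#' proportions of the parent within one sample per class. Deterministic given
#' `seed`.
#'
#' @param dataset A [cohort_dataset()].
#' @param test_fraction Test proportion in (0, 1); default 0.2 (an 80/20
#'   split).
#' @param seed Integer seed.
#' @return A list of class `split_pair` with elements `train`, `test` and
#'   `fraction`.
#' @export
stratified_split <- function(dataset, test_fraction = 0.2, seed = 1L) {
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must lie in (0, 1)")
  y <- dataset$labels
  if (any(table(y) < 2)) abort("each class needs at least 2 samples to split")
  test <- stratified_test_indices(y, test_fraction, seed)
  train <- setdiff(seq_along(y), test)
  structure(
    list(train = cohort_subset(dataset, rows = train),
         test = cohort_subset(dataset, rows = test),
         fraction = test_fraction),
    class = "split_pair")
}

#' Stratified k-fold cross-validation indices
#'
#' Partitions samples into `k` stratified folds: validation folds are
#' disjoint, cover all samples, per-class counts differ by at most one
#' across folds. Deterministic given `seed`.
#'
#' @param dataset A [cohort_dataset()] (or a label vector).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` lists, each with integer vectors `train` and
#'   `validation`.
#' @export
kfold_indices <- function(dataset, k = 5, seed = 1L) {
  y <- if (inherits(dataset, "cohort_dataset")) dataset$labels else as.integer(dataset)
  assert_that(k >= 2, "k must be >= 2")
  if (k > length(y)) abort("k must not exceed the sample count")
  withr::local_seed(seed)
  fold <- integer(length(y))
  pos <- 0L
  for (cls in sort(unique(y))) {
    cls_idx <- which(y == cls)
    idx <- cls_idx[sample.int(length(cls_idx))]
    # continue the cyclic fold assignment across classes so overall fold
    # sizes (not just per-class counts) differ by at most one
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), validation = which(fold == f))
  })
}
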