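#' Cohort genotype dataset
#'
#' Container for one cohort's genotype dosage matrix together with its binary
#' case/control labels. Dosages count minor alleles (0, 1 or 2); missing
#' genotypes are `NA` in the matrix and flagged in `missing_mask`. Columns are
#' named by rsID, rows by sample identifier.
#'
#' @param genotypes Numeric matrix, samples x SNPs, entries in \{0, 1, 2\} or
#'   `NA`. Column names are taken as rsIDs when `rsids` is not given.
#' @param labels Binary vector (0 = control, 1 = case), one per sample.
#' @param name Cohort identifier string.
#' @param rsids Character vector of unique SNP identifiers, one per column.
#' @param sample_ids Character vector of unique sample identifiers.
#'
#' @return An object of class `cohort_dataset`: a list with elements
#'   `name`, `genotypes`, `rsids`, `labels`, `sample_ids` and `missing_mask`.
#' @export
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 2), nrow = 3,
#'             dimnames = list(NULL, c("rs000001", "rs000002")))
#' cohort_dataset(g, labels = c(0, 1, 1), name = "toy")
cohort_dataset <- function(genotypes, labels, name = "cohort",
                           rsids = colnames(genotypes),
                           sample_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(rsids)) rsids <- sprintf("rs%06d", seq_len(ncol(genotypes)))
  rsids <- as.character(rsids)
  if (is.null(sample_ids)) sample_ids <- sprintf("%s_s%04d", name, seq_len(nrow(genotypes)))
  labels <- as.integer(labels)

  assert_that(length(rsids) == ncol(genotypes),
              "rsids length must equal the genotype column count")
  assert_that(length(labels) == nrow(genotypes),
              "labels length must equal the genotype row count")
  assert_that(length(sample_ids) == nrow(genotypes),
              "sample_ids length must equal the genotype row count")
  dup <- rsids[duplicated(rsids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate rsID(s): ", paste(unique(dup), collapse = ", ")))
  }
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  obs <- genotypes[!is.na(genotypes)]
  assert_that(all(obs %in% c(0, 1, 2) | (obs >= 0 & obs <= 2)),
              "dosages must lie in [0, 2]")

  dimnames(genotypes) <- list(sample_ids, rsids)
  structure(
    list(name = as.character(name),
         genotypes = genotypes,
         rsids = rsids,
         labels = labels,
         sample_ids = as.character(sample_ids),
         missing_mask = is.na(genotypes)),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  n_miss <- sum(x$missing_mask)
  cat(sprintf(
    "<cohort_dataset '%s': %d samples x %d SNPs; %d cases / %d controls; %s missing>\n",
    x$name, nrow(x$genotypes), ncol(x$genotypes),
    sum(x$labels == 1L), sum(x$labels == 0L),
    sprintf("%.2f%%", 100 * n_miss / length(x$genotypes))))
  invisible(x)
}

#' @export
dim.cohort_dataset <- function(x) dim(x$genotypes)

#' Coerce a cohort dataset to a tibble
#'
#' Long-friendly wide layout: one row per sample with `sample_id`, `label`
#' and one dosage column per rsID (the on-disk CSV layout).
#'
#' @param x A [cohort_dataset()].
#' @param ... Unused.
#' @return A tibble with `nrow(x)` rows.
#' @export
as_tibble.cohort_dataset <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$genotypes), .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = x$sample_ids, label = x$labels), out)
}

# subset rows (samples) and/or columns (SNPs) of a cohort, keeping metadata
cohort_subset <- function(x, rows = NULL, cols = NULL, name = x$name) {
  g <- x$genotypes
  labels <- x$labels
  ids <- x$sample_ids
  if (!is.null(rows)) {
    g <- g[rows, , drop = FALSE]
    labels <- labels[rows]
    ids <- ids[rows]
  }
  if (!is.null(cols)) g <- g[, cols, drop = FALSE]
  cohort_dataset(g, labels, name = name, rsids = colnames(g), sample_ids = ids)
}

# row-bind cohorts sharing an rsID universe (used for source/target pooling)
cohort_rbind <- function(datasets, name = NULL) {
  assert_that(length(datasets) >= 1, "need at least one dataset")
  rs <- datasets[[1]]$rsids
  for (d in datasets) {
    assert_that(identical(d$rsids, rs),
                "cohorts must be harmonised (identical rsID order) before pooling")
  }
  if (is.null(name)) name <- paste(vapply(datasets, `[[`, "", "name"), collapse = "+")
  g <- do.call(rbind, lapply(datasets, `[[`, "genotypes"))
  labels <- unlist(lapply(datasets, `[[`, "labels"), use.names = FALSE)
  ids <- unlist(lapply(datasets, `[[`, "sample_ids"), use.names = FALSE)
  if (anyDuplicated(ids)) ids <- sprintf("%s_s%05d", name, seq_along(ids))
  cohort_dataset(g, labels, name = name, rsids = rs, sample_ids = ids)
}
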