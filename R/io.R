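#' Read a genotype table as a cohort dataset
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`csv`}{Header `sample_id,label,rs...`; `label` is 0/1; dosage cells
#'     are 0/1/2 (real values in [0, 2] are accepted, e.g. imputed dosages).}
#'   \item{`plink_raw`}{Whitespace table in PLINK `--recode A` style: columns
#'     `FID IID PAT MAT SEX PHENOTYPE` then one `rsID_allele` dosage column
#'     per SNP. `PHENOTYPE` 1/2 is recoded to 0/1; `-9` or `NA` phenotypes
#'     drop the row with a warning.}
#' }
#' Unparseable or out-of-range dosage cells become missing (with a warning)
#' and are flagged in the dataset's `missing_mask`. Duplicate rsIDs are an
#' error naming the offender.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"plink_raw"`.
#' @param name Cohort name; defaults to the file stem.
#' @return A [cohort_dataset()].
#' @export
read_genotypes <- function(path, format = c("csv", "plink_raw"),
                           name = tools::file_path_sans_ext(basename(path))) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (file.size(path) == 0) abort(paste0("empty file: ", path))

  if (format == "csv") {
    raw <- read.csv(path, check.names = FALSE, colClasses = "character")
    if (nrow(raw) == 0) abort(paste0("no samples in file: ", path))
    assert_that(all(c("sample_id", "label") %in% names(raw)),
                "csv genotype files need 'sample_id' and 'label' columns")
    rsids <- names(raw)[!names(raw) %in% c("sample_id", "label")]
    labels <- suppressWarnings(as.numeric(raw$label))
    if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
      abort("labels must be binary 0/1")
    }
    sample_ids <- raw$sample_id
    geno_chr <- as.matrix(raw[, rsids, drop = FALSE])
  } else {
    raw <- read.table(path, header = TRUE, check.names = FALSE,
                      colClasses = "character")
    if (nrow(raw) == 0) abort(paste0("no samples in file: ", path))
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    assert_that(all(fixed %in% names(raw)),
                "plink_raw files need FID IID PAT MAT SEX PHENOTYPE columns")
    pheno <- suppressWarnings(as.numeric(raw$PHENOTYPE))
    drop <- is.na(pheno) | pheno == -9
    if (any(drop)) {
      warn(sprintf("dropping %d sample(s) with missing phenotype", sum(drop)))
      raw <- raw[!drop, , drop = FALSE]
      pheno <- pheno[!drop]
      if (nrow(raw) == 0) abort("all samples had missing phenotypes")
    }
    if (!all(pheno %in% c(1, 2))) abort("labels must be binary (PHENOTYPE 1/2)")
    labels <- pheno - 1
    cols <- names(raw)[!names(raw) %in% fixed]
    # strip the counted-allele suffix, e.g. rs123_A -> rs123
    rsids <- sub("_[ACGT0-9]+$", "", cols)
    sample_ids <- raw$IID
    geno_chr <- as.matrix(raw[, cols, drop = FALSE])
  }

  dup <- rsids[duplicated(rsids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate rsID(s): ", paste(unique(dup), collapse = ", ")))
  }
  g <- suppressWarnings(matrix(as.numeric(geno_chr),
                               nrow = nrow(geno_chr), ncol = ncol(geno_chr)))
  bad <- !is.na(g) & (g < 0 | g > 2)
  n_unparseable <- sum(is.na(g) & !is.na(geno_chr) & geno_chr != "NA" & geno_chr != "")
  if (any(bad) || n_unparseable > 0) {
    warn(sprintf("%d dosage cell(s) unparseable or out of [0, 2]; set missing",
                 sum(bad) + n_unparseable))
    g[bad] <- NA_real_
  }
  cohort_dataset(g, labels, name = name, rsids = rsids, sample_ids = sample_ids)
}

#' Write a cohort dataset as CSV or PLINK `.raw` text
#'
#' Inverse of [read_genotypes()]: a written file round-trips to an identical
#' dosage matrix, rsID order and labels.
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output path.
#' @param format `"csv"` or `"plink_raw"`.
#' @param allele Counted-allele suffix appended to rsIDs in `plink_raw`
#'   column headers.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dataset, path, format = c("csv", "plink_raw"),
                            allele = "A") {
  format <- match.arg(format)
  g <- dataset$genotypes
  if (format == "csv") {
    df <- data.frame(sample_id = dataset$sample_ids, label = dataset$labels,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(g, check.names = FALSE))
    write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    df <- data.frame(FID = dataset$sample_ids, IID = dataset$sample_ids,
                     PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = dataset$labels + 1L, check.names = FALSE)
    gdf <- as.data.frame(g, check.names = FALSE)
    names(gdf) <- paste0(dataset$rsids, "_", allele)
    df <- cbind(df, gdf)
    write.table(df, path, row.names = FALSE, quote = FALSE, sep = " ", na = "NA")
  }
  invisible(path)
}

#' Write or read simulation ground truth as JSON
#'
#' @param truth A `ground_truth` object from [simulate_cohorts()].
#' @param path JSON path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns a `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    causal_indices = truth$causal_indices,
    causal_rsids = truth$causal_rsids,
    effect_sizes = truth$effect_sizes,
    epistatic_pairs = truth$epistatic_pairs,
    per_cohort_mafs = truth$per_cohort_mafs,
    rsids = truth$rsids)
  jsonlite::write_json(out, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$per_cohort_mafs)) {
    x$per_cohort_mafs <- as.matrix(x$per_cohort_mafs)
    colnames(x$per_cohort_mafs) <- x$rsids
  }
  if (!is.null(x$epistatic_pairs) && length(x$epistatic_pairs) > 0) {
    x$epistatic_pairs <- matrix(as.numeric(as.matrix(x$epistatic_pairs)), ncol = 3)
  }
  structure(x, class = "ground_truth")
}
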