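#' Shapley-value attribution of student predictions
#'
#' Estimates per-sample, per-SNP Shapley values for the student model's
#' positive-class probability, against a background sample. Two in-package
#' estimators are provided:
#' \describe{
#'   \item{`sampling`}{Permutation sampling with antithetic pairs: for each
#'     drawn background row and feature permutation, features are switched
#'     from background to explained values one at a time and the marginal
#'     probability changes are accredited; the reversed permutation is
#'     evaluated alongside. Local accuracy holds by construction: per
#'     sample, attributions sum to `f(x)` minus the mean background
#'     prediction, up to floating point.}
#'   \item{`kernel`}{Weighted-least-squares regression over sampled feature
#'     coalitions with Shapley-kernel weights, with the local-accuracy
#'     constraint eliminated exactly.}
#' }
#' Deterministic given `seed`.
#'
#' @param student A trained student `wdnn_model` (or any model accepted by
#'   `predict_fn`).
#' @param background Matrix (or [cohort_dataset()]) of background samples
#'   defining the reference distribution.
#' @param explain Matrix (or [cohort_dataset()]) of samples to attribute.
#' @param method `"sampling"` or `"kernel"`.
#' @param n_perm Permutation draws per explained sample (sampling method;
#'   antithetic pairing doubles the effective count).
#' @param n_coalitions Sampled coalitions (kernel method).
#' @param seed Integer seed.
#' @param cohort Cohort label stored in the summary.
#' @param predict_fn Optional function(matrix) -> probability vector;
#'   defaults to the student's forward pass.
#' @return An `attribution_summary`: list with `cohort`, `rsids`,
#'   `mean_abs_shap`, `per_sample_shap` (n x p), `base_value`, `fx`,
#'   `background_size` and `method`.
#' @export
attribute_student <- function(student, background, explain,
                              method = c("sampling", "kernel"),
                              n_perm = 32, n_coalitions = 1024, seed = 1L,
                              cohort = "cohort", predict_fn = NULL) {
  method <- match.arg(method)
  rsids <- NULL
  if (inherits(background, "cohort_dataset")) background <- background$genotypes
  if (inherits(explain, "cohort_dataset")) {
    rsids <- explain$rsids
    explain <- explain$genotypes
  }
  background <- as.matrix(background); explain <- as.matrix(explain)
  if (ncol(background) != ncol(explain)) {
    abort("background and explain matrices must share the feature space")
  }
  assert_that(nrow(background) >= 1, "background must be non-empty")
  p <- ncol(explain)
  if (is.null(rsids)) rsids <- colnames(explain) %||% sprintf("rs%06d", seq_len(p))
  if (is.null(predict_fn)) {
    assert_that(inherits(student, "wdnn_model"), "student must be a wdnn_model")
    assert_that(student$config$n_snps == p, "feature count mismatch with model")
    predict_fn <- function(M) wdnn_forward(student, M)$probabilities
  }
  withr::local_seed(seed)

  # per-row draw seed derived from the row's content (not its position), so
  # attributions are invariant to the order of the explain set
  content_seed <- function(x) {
    derive_seed(seed, as.integer(round(sum(x * (seq_along(x) %% 31 + 1)) * 97)) %% 100003L)
  }

  n <- nrow(explain)
  phi <- matrix(0, n, p, dimnames = list(NULL, rsids))
  fx <- as.numeric(predict_fn(explain))
  base_vals <- numeric(n)

  if (method == "sampling") {
    half <- max(1L, n_perm %/% 2L)
    for (s in seq_len(n)) {
      x <- explain[s, ]
      # stage all permutation walks of this sample into one model call
      orders <- vector("list", 2L * half)
      blocks <- vector("list", 2L * half)
      withr::with_seed(content_seed(x), {
        for (r in seq_len(half)) {
          b <- background[sample.int(nrow(background), 1L), ]
          perm <- sample.int(p)
          for (a in 1:2) {
            ord <- if (a == 1) perm else rev(perm)
            # rows: background, then features switched to x one at a time
            Z <- matrix(b, p + 1, p, byrow = TRUE)
            for (k in seq_len(p)) {
              Z[(k + 1):(p + 1), ord[k]] <- x[ord[k]]
            }
            orders[[2 * (r - 1) + a]] <- ord
            blocks[[2 * (r - 1) + a]] <- Z
          }
        }
      })
      v <- predict_fn(do.call(rbind, blocks))
      contrib <- numeric(p)
      base_acc <- 0
      for (i in seq_along(orders)) {
        vi <- v[((i - 1) * (p + 1) + 1):(i * (p + 1))]
        contrib[orders[[i]]] <- contrib[orders[[i]]] + diff(vi)
        base_acc <- base_acc + vi[1]
      }
      phi[s, ] <- contrib / (2 * half)
      base_vals[s] <- base_acc / (2 * half)
    }
  } else {
    base_vals <- rep(mean(predict_fn(background)), n)
    phi <- kernel_shap(predict_fn, background, explain, fx, base_vals[1],
                       n_coalitions)
    dimnames(phi) <- list(NULL, rsids)
  }

  structure(
    list(cohort = cohort, rsids = rsids,
         mean_abs_shap = colMeans(abs(phi)),
         per_sample_shap = phi,
         base_value = base_vals, fx = fx,
         background_size = nrow(background),
         method = method),
    class = "attribution_summary")
}

# KernelSHAP: weighted least squares over sampled coalitions with the
# local-accuracy constraint eliminated through the last feature
kernel_shap <- function(predict_fn, background, explain, fx, f0, n_coalitions) {
  p <- ncol(explain)
  n <- nrow(explain)
  sizes <- seq_len(p - 1)
  kw <- (p - 1) / (choose(p, sizes) * sizes * (p - sizes))
  size_prob <- kw * choose(p, sizes)
  size_prob <- size_prob / sum(size_prob)

  draw <- sample(sizes, n_coalitions, replace = TRUE, prob = size_prob)
  Zmask <- t(vapply(draw, function(k) {
    z <- logical(p); z[sample.int(p, k)] <- TRUE; z
  }, logical(p)))
  w <- kw[draw]

  phi <- matrix(0, n, p)
  nb <- nrow(background)
  for (s in seq_len(n)) {
    x <- explain[s, ]
    # v(S): mean prediction with S taken from x, complement from background
    v <- vapply(seq_len(n_coalitions), function(i) {
      M <- background
      M[, Zmask[i, ]] <- matrix(x[Zmask[i, ]], nb, sum(Zmask[i, ]), byrow = TRUE)
      mean(predict_fn(M))
    }, numeric(1))
    yv <- v - f0 - Zmask[, p] * (fx[s] - f0)
    A <- Zmask[, -p, drop = FALSE] - Zmask[, p]
    fit <- stats::lm.wfit(A * 1, yv, w)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    phi[s, ] <- c(co, fx[s] - f0 - sum(co))
  }
  phi
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat(sprintf(
    "<attribution_summary '%s': %d samples x %d SNPs (%s, background %d)>\n",
    x$cohort, nrow(x$per_sample_shap), length(x$rsids), x$method,
    x$background_size))
  print(head(tidy(x), 5))
  invisible(x)
}

#' Tidy an attribution summary
#'
#' @param x An `attribution_summary`.
#' @param ... Unused.
#' @return A tibble of `rsid`, `mean_abs_shap` and `rank` (1 = largest
#'   impact, ties broken lexicographically by rsID).
#' @export
tidy.attribution_summary <- function(x, ...) {
  out <- tibble(rsid = x$rsids, mean_abs_shap = unname(x$mean_abs_shap))
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_abs_shap), .data$rsid)
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Top-impact SNPs of an attribution summary
#'
#' @param summary An `attribution_summary`.
#' @param k Number of SNPs (1 to the panel size).
#' @return Character vector of rsIDs ordered by descending mean absolute
#'   Shapley value, ties lexicographic.
#' @export
top_k_snps <- function(summary, k = 20) {
  p <- length(summary$rsids)
  if (k <= 0) abort("k must be positive")
  assert_that(k <= p, "k must not exceed the SNP panel size")
  head(tidy(summary)$rsid, k)
}

#' Cross-cohort presence of top-attributed SNPs
#'
#' For every SNP in any cohort's top-`k` attribution list, records which
#' cohorts rank it top-`k` and its best (smallest) rank, sorted by breadth
#' of presence then best rank — the cross-cohort transferability view of
#' the attribution results.
#'
#' @param summaries Named list (>= 2) of `attribution_summary` objects over
#'   an identical rsID universe.
#' @param k Per-cohort top-list size.
#' @return A tibble of class `presence_table`: `rsid`,
#'   `cohorts_present` (list column), `n_cohorts`, `best_rank`.
#' @export
cross_cohort_presence <- function(summaries, k = 20) {
  assert_that(length(summaries) >= 2, "need at least two cohorts")
  universe <- summaries[[1]]$rsids
  for (s in summaries) {
    if (!setequal(s$rsids, universe)) {
      abort("attribution summaries have inconsistent rsID universes; harmonise first")
    }
  }
  if (is.null(names(summaries))) {
    names(summaries) <- vapply(summaries, `[[`, "", "cohort")
  }
  tops <- purrr::imap_dfr(summaries, function(s, nm) {
    td <- head(tidy(s), k)
    dplyr::mutate(td, cohort = nm)
  })
  out <- tops |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(cohorts_present = list(sort(unique(.data$cohort))),
                     n_cohorts = dplyr::n_distinct(.data$cohort),
                     best_rank = min(.data$rank), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_cohorts), .data$best_rank, .data$rsid)
  class(out) <- c("presence_table", class(out))
  out
}

#' Write an attribution summary or presence table as TSV
#'
#' @param x An `attribution_summary` or `presence_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(x, path) {
  df <- if (inherits(x, "attribution_summary")) {
    as.data.frame(tidy(x))
  } else {
    out <- as.data.frame(x)
    out$cohorts_present <- vapply(x$cohorts_present, paste, "", collapse = ",")
    out
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
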