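# rank-statistic AUC with half credit for ties (Wilcoxon form)
#' Area under the ROC curve by the rank statistic
#'
#' @param labels 0/1 labels.
#' @param scores Positive-class scores.
#' @return AUC in [0, 1]; ties receive half credit. `NA` (with a warning)
#'   when only one class is present.
#' @export
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined with a single class; returning NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

macro_f1 <- function(labels, predictions) {
  f1s <- vapply(c(0, 1), function(cls) {
    tp <- sum(predictions == cls & labels == cls)
    fp <- sum(predictions == cls & labels != cls)
    fn <- sum(predictions != cls & labels == cls)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  mean(f1s)
}

roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- !duplicated(scores[ord][seq_along(y)], fromLast = TRUE)
  tibble(fpr = c(0, fp[keep] / max(n0, 1), 1),
         tpr = c(0, tp[keep] / max(n1, 1), 1))
}

#' Classification metrics for one model on one target
#'
#' Computes the full metric panel from labels, thresholded predictions and
#' continuous scores: accuracy, macro-averaged precision/recall/F1 over the
#' two classes, specificity (true-negative rate), rank-statistic AUC with
#' half credit for ties, the 2 x 2 confusion matrix (TN, FP / FN, TP) and
#' ROC points. The decision threshold is 0.5 on `scores` when `predictions`
#' is omitted.
#'
#' @param labels 0/1 labels.
#' @param predictions 0/1 predicted classes (default: `scores >= 0.5`).
#' @param scores Positive-class probabilities in [0, 1].
#' @param model_name Identifier stored in the report (e.g. `"teacher"`,
#'   `"rf"`).
#' @return An `evaluation_report` object; see [tidy()] and [glance()]
#'   methods.
#' @export
#' @examples
#' compute_metrics(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
#'                 c(0, 0, 0, 1, 0, 0, 1, 1, 1, 1),
#'                 scores = c(.1, .2, .3, .6, .4, .45, .7, .8, .9, .95))
compute_metrics <- function(labels, predictions = NULL, scores,
                            model_name = "model") {
  assert_that(length(labels) == length(scores), "length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be binary 0/1")
  assert_that(all(scores >= 0 & scores <= 1), "scores must lie in [0, 1]")
  if (is.null(predictions)) predictions <- as.integer(scores >= 0.5)
  assert_that(length(predictions) == length(labels), "length mismatch")

  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  tp <- sum(predictions == 1 & labels == 1)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                      dimnames = list(c("true_0", "true_1"),
                                      c("pred_0", "pred_1")))

  per_class <- function(cls) {
    tpc <- sum(predictions == cls & labels == cls)
    fpc <- sum(predictions == cls & labels != cls)
    fnc <- sum(predictions != cls & labels == cls)
    prec <- if (tpc + fpc > 0) tpc / (tpc + fpc) else 0
    rec <- if (tpc + fnc > 0) tpc / (tpc + fnc) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  pc <- (per_class(0) + per_class(1)) / 2

  structure(
    list(model_name = model_name,
         accuracy = (tp + tn) / length(labels),
         precision = pc[1], recall = pc[2], f1 = pc[3],
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         auc = auc_rank(labels, scores),
         confusion = confusion,
         roc_points = roc_points(labels, scores),
         n = length(labels)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report '%s' (n = %d): acc %.3f, prec %.3f, rec %.3f, F1 %.3f, spec %.3f, AUC %s>\n",
    x$model_name, x$n, x$accuracy, x$precision, x$recall, x$f1,
    x$specificity, ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble of `metric`, `value`. `glance()`: a
#'   one-row tibble of all scalar metrics.
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble(model = x$model_name,
         metric = c("accuracy", "precision", "recall", "f1", "specificity", "auc"),
         value = c(x$accuracy, x$precision, x$recall, x$f1, x$specificity, x$auc))
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(model = x$model_name, accuracy = x$accuracy, precision = x$precision,
         recall = x$recall, f1 = x$f1, specificity = x$specificity,
         auc = x$auc, n = x$n)
}

#' Train a downstream classifier on extracted features
#'
#' Fits one of the standard tree-ensemble learners on a real-valued feature matrix
#' (typically teacher activations from [extract_features()]): `rf` (random
#' forest), `dt` (CART decision tree), `gb` (conservative gradient-boosted
#' trees: depth 3, learning rate 0.1) or `xgboost` (default boosted trees).
#' Deterministic given `seed` (single-threaded boosting).
#'
#' @param features Numeric matrix, samples x features, finite entries.
#' @param labels 0/1 labels.
#' @param kind One of `"gb"`, `"dt"`, `"rf"`, `"xgboost"`.
#' @param seed Integer seed.
#' @return A `downstream_model`; use [predict()] with `type = "prob"` or
#'   `"class"`.
#' @export
train_downstream <- function(features, labels, kind = c("rf", "dt", "gb", "xgboost"),
                             seed = 1L) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  if (any(!is.finite(features))) abort("features must be finite (no NaN/NA)")
  assert_that(nrow(features) >= 10, "need at least 10 samples")
  assert_that(length(labels) == nrow(features), "label/feature length mismatch")
  # constant columns carry no signal and can stall the forest's split search
  keep <- which(matrixStats_colSds(features) > 0)
  if (length(keep) == 0) {
    warn("all feature columns are constant; fitting a prior-only classifier")
    return(structure(list(kind = kind, fit = NULL, keep = keep,
                          prior = mean(labels), n_features = ncol(features)),
                     class = "downstream_model"))
  }
  full_p <- ncol(features)
  features <- features[, keep, drop = FALSE]
  colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  withr::local_seed(seed)

  fit <- switch(
    kind,
    rf = randomForest::randomForest(x = features, y = factor(labels, levels = c(0, 1))),
    dt = {
      df <- data.frame(.label = factor(labels, levels = c(0, 1)), features)
      rpart::rpart(.label ~ ., data = df, method = "class")
    },
    gb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                    subsample = 1, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(features, label = labels, nthread = 1),
      nrounds = 150, verbose = 0),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(features, label = labels, nthread = 1),
      nrounds = 100, verbose = 0))

  structure(list(kind = kind, fit = fit, keep = keep, prior = mean(labels),
                 n_features = full_p),
            class = "downstream_model")
}

# per-column standard deviations without the matrixStats dependency
matrixStats_colSds <- function(m) {
  apply(m, 2, stats::sd)
}

#' @export
predict.downstream_model <- function(object, newdata, type = c("prob", "class"),
                                     ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(object$fit)) {
    prob <- rep(object$prior, nrow(newdata))
    return(if (type == "prob") prob else as.integer(prob >= 0.5))
  }
  newdata <- newdata[, object$keep, drop = FALSE]
  colnames(newdata) <- sprintf("f%03d", seq_len(ncol(newdata)))
  prob <- switch(
    object$kind,
    rf = unname(predict(object$fit, newdata, type = "prob")[, "1"]),
    dt = unname(predict(object$fit, data.frame(newdata), type = "prob")[, "1"]),
    gb = ,
    xgboost = as.numeric(predict(object$fit,
                                 xgboost::xgb.DMatrix(newdata, nthread = 1))))
  if (type == "prob") prob else as.integer(prob >= 0.5)
}

#' Define a transfer scenario
#'
#' The four cohort configurations: single source to single target
#' (`exp1_single_to_single`), aggregated source to single target
#' (`exp2_aggregated_to_single`), single source to aggregated target
#' (`exp3_single_to_aggregated`) and fully aggregated transfer
#' (`exp4_aggregated_to_aggregated`). Source and target cohort sets must be
#' disjoint and non-empty.
#'
#' @param id Scenario identifier (see above); inferred from the cohort
#'   counts when `NULL`.
#' @param source_cohorts,target_cohorts Character vectors of cohort names.
#' @return A `transfer_scenario` object.
#' @export
transfer_scenario <- function(source_cohorts, target_cohorts, id = NULL) {
  assert_that(length(source_cohorts) >= 1 && length(target_cohorts) >= 1,
              "source and target cohort sets must be non-empty")
  if (length(intersect(source_cohorts, target_cohorts)) > 0) {
    abort("source and target cohort sets must be disjoint")
  }
  if (is.null(id)) {
    id <- paste0(
      "exp", 1 + (length(source_cohorts) > 1) + 2 * (length(target_cohorts) > 1),
      "_", if (length(source_cohorts) > 1) "aggregated" else "single",
      "_to_", if (length(target_cohorts) > 1) "aggregated" else "single")
  }
  structure(list(id = id, source_cohorts = source_cohorts,
                 target_cohorts = target_cohorts),
            class = "transfer_scenario")
}

#' Cross-product pairs from the top F-score SNPs
#'
#' Builds the default wide-path feature map: all pairwise combinations of
#' the `n_top` highest F-score SNPs, whose dosage products feed the wide
#' component of a Wide-Deep model.
#'
#' @param dataset An imputed [cohort_dataset()].
#' @param n_top Number of top-ranked SNPs to pair (`choose(n_top, 2)`
#'   products).
#' @return Two-column matrix of SNP index pairs, or `NULL` when fewer than
#'   two SNPs are available.
#' @export
top_fscore_pairs <- function(dataset, n_top = 10) {
  n_top <- min(n_top, ncol(dataset$genotypes))
  if (n_top < 2) return(NULL)
  top <- head(dplyr::arrange(f_score(dataset), .data$rank, .data$rsid)$rsid, n_top)
  idx <- match(top, dataset$rsids)
  t(utils::combn(idx, 2))
}

#' Run one transfer-learning scenario end to end
#'
#' Executes the full teacher-student pipeline: pool and 80/20-split the
#' source; impute (train statistics only) and balance the source training
#' partition; train the Wide-Deep teacher with early stopping on the source
#' test split; 80/20-split the target, distil the student on the balanced
#' target training split using the source teacher's soft targets (with
#' optional 5-fold alpha tuning when the distillation config carries a
#' grid); extract teacher features; fit the four tree classifiers on
#' source-train features; and evaluate all six models on the held-out
#' target test split. Target test samples never reach any fitting input,
#' imputation statistic or balancing step; the returned `audit` proves it.
#'
#' @param scenario A [transfer_scenario()].
#' @param cohorts Named list of [cohort_dataset()]s covering all scenario
#'   cohort names (harmonised or harmonisable).
#' @param distill_cfg A [distill_config()].
#' @param seed Master seed; all internal seeds derive from it.
#' @param teacher_opts Overrides for [teacher_config()] (e.g.
#'   `list(use_attention = FALSE, embedding_dim = 8)`).
#' @param student_reduction Shrink factors for [build_student()].
#' @param train_opts Overrides for teacher training (`epochs`,
#'   `batch_size`, `learning_rate`, `patience`).
#' @param balance Balance the training partitions (two-stage over/under
#'   sampling).
#' @param balance_eval Also balance the evaluation split (reproduces
#'   balanced-evaluation variants).
#' @param eval_full_target Evaluate on the full target cohort rather than
#'   its held-out split (the alternative reading of the protocol; the
#'   student still trains only on the target training partition).
#' @param n_wide_pairs Top F-score SNP count whose pairwise dosage products
#'   feed the wide path.
#' @return A `scenario_result`: list with `reports` (one
#'   `evaluation_report` per model), `scenario`, `alpha`, `seeds`, `audit`
#'   and the fitted `teacher`/`student`.
#' @export
run_scenario <- function(scenario, cohorts,
                         distill_cfg = distill_config(),
                         seed = 1L,
                         teacher_opts = list(),
                         student_reduction = list(heads = 0.5, layers = 0.5,
                                                  width = 0.5, embed = 0.5),
                         train_opts = list(),
                         balance = TRUE, balance_eval = FALSE,
                         eval_full_target = FALSE,
                         n_wide_pairs = 10) {
  assert_that(inherits(scenario, "transfer_scenario"),
              "scenario must be a transfer_scenario")
  needed <- c(scenario$source_cohorts, scenario$target_cohorts)
  missing_cohorts <- setdiff(needed, names(cohorts))
  if (length(missing_cohorts) > 0) {
    abort(paste0("cohorts not supplied: ", paste(missing_cohorts, collapse = ", ")))
  }
  cohorts <- if (length(cohorts[needed]) > 1) {
    setNames(harmonise_cohorts(cohorts[needed]), needed)
  } else cohorts[needed]

  source <- cohort_rbind(cohorts[scenario$source_cohorts], name = "source")
  target <- cohort_rbind(cohorts[scenario$target_cohorts], name = "target")

  fit_ids <- character(0)   # every sample id that reaches a fitting input
  tr_opts <- utils::modifyList(
    list(epochs = 30, batch_size = 64, learning_rate = 0.01, patience = 10),
    train_opts)

  # --- source side -----------------------------------------------------------
  src_split <- stratified_split(source, 0.2, seed = derive_seed(seed, 1))
  src_means <- snp_means(src_split$train)
  src_train <- impute_missing(src_split$train, "mean")
  src_val <- impute_missing(src_split$test, "mean", stats = src_means)
  if (balance) {
    src_train <- balance_classes(src_train, seed = derive_seed(seed, 2))
  }
  fit_ids <- c(fit_ids, source$sample_ids)   # all source rows may be fit on

  pairs <- if (n_wide_pairs >= 2) top_fscore_pairs(src_train, n_wide_pairs)
  tcfg <- do.call(teacher_config,
                  c(list(n_snps = ncol(src_train$genotypes), cross_pairs = pairs),
                    teacher_opts))
  teacher <- train_wdnn(
    wdnn_init(tcfg, seed = derive_seed(seed, 3)),
    src_train, X_val = src_val,
    epochs = tr_opts$epochs, batch_size = tr_opts$batch_size,
    learning_rate = tr_opts$learning_rate, patience = tr_opts$patience,
    seed = derive_seed(seed, 4))

  # --- target side -----------------------------------------------------------
  tgt_split <- stratified_split(target, 0.2, seed = derive_seed(seed, 5))
  tgt_means <- snp_means(tgt_split$train)
  tgt_train <- impute_missing(tgt_split$train, "mean")
  tgt_test <- impute_missing(
    if (eval_full_target) target else tgt_split$test, "mean", stats = tgt_means)
  if (balance) {
    tgt_train <- balance_classes(tgt_train, seed = derive_seed(seed, 6))
  }
  if (balance_eval) {
    tgt_test <- balance_classes(tgt_test, seed = derive_seed(seed, 7))
  }
  fit_ids <- c(fit_ids, tgt_train$sample_ids)

  dcfg <- distill_cfg
  dcfg$seed <- derive_seed(seed, 8)
  inner <- stratified_split(tgt_train, 0.15, seed = derive_seed(seed, 9))
  student0 <- build_student(tcfg, reduction = student_reduction,
                            seed = derive_seed(seed, 10))
  if (length(dcfg$alpha_grid) > 1) {
    # 5-fold alpha selection on the target training partition
    folds <- kfold_indices(tgt_train, k = 5, seed = derive_seed(seed, 11))
    mean_f1 <- vapply(dcfg$alpha_grid, function(a) {
      cfg_a <- dcfg; cfg_a$alpha <- a; cfg_a$alpha_grid <- a
      mean(vapply(folds, function(f) {
        fit <- train_student(teacher, student0,
                             cohort_subset(tgt_train, rows = f$train),
                             cohort_subset(tgt_train, rows = f$validation),
                             config = cfg_a)
        utils::tail(fit$history$val_f1, 1)
      }, numeric(1)))
    }, numeric(1))
    ord <- order(-mean_f1, dcfg$alpha_grid)
    dcfg$alpha <- dcfg$alpha_grid[ord[1]]
  }
  student <- train_student(teacher, student0, inner$train, inner$test,
                           config = dcfg)

  # --- downstream classifiers on teacher features ----------------------------
  feat_train <- extract_features(teacher, src_train)
  feat_test <- extract_features(teacher, tgt_test)
  reports <- list()
  for (kind in c("gb", "dt", "rf", "xgboost")) {
    fit <- train_downstream(feat_train, src_train$labels, kind = kind,
                            seed = derive_seed(seed, 20 + match(kind, c("gb", "dt", "rf", "xgboost"))))
    prob <- predict(fit, feat_test, type = "prob")
    reports[[kind]] <- compute_metrics(tgt_test$labels, scores = prob,
                                       model_name = kind)
  }
  reports$teacher <- compute_metrics(
    tgt_test$labels, scores = teacher_forward(teacher, tgt_test)$probabilities,
    model_name = "teacher")
  reports$student <- compute_metrics(
    tgt_test$labels, scores = teacher_forward(student, tgt_test)$probabilities,
    model_name = "student")
  reports <- reports[c("teacher", "student", "gb", "dt", "rf", "xgboost")]

  test_ids <- tgt_split$test$sample_ids
  audit <- list(
    fit_ids = unique(fit_ids),
    test_ids = test_ids,
    leakage_free = length(intersect(unique(fit_ids), test_ids)) == 0)
  if (!eval_full_target && !audit$leakage_free) {
    abort("leakage audit failed: target test rows reached a fitting input")
  }

  structure(
    list(reports = reports, scenario = scenario, alpha = dcfg$alpha,
         temperature = dcfg$temperature, seed = seed, audit = audit,
         teacher = teacher, student = student),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s: %s -> %s (alpha = %.2f, T = %.1f)>\n",
              x$scenario$id,
              paste(x$scenario$source_cohorts, collapse = "+"),
              paste(x$scenario$target_cohorts, collapse = "+"),
              x$alpha, x$temperature))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a scenario result into the published table layout
#'
#' One row per model with accuracy, macro precision/recall/F1, specificity
#' and AUC (the Source/Target, Model, Acc, Prec, Rec, F1, Spec layout).
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return A tibble with one row per evaluated model.
#' @export
tidy.scenario_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$reports, glance)) |>
    dplyr::mutate(
      source = paste(x$scenario$source_cohorts, collapse = "+"),
      target = paste(x$scenario$target_cohorts, collapse = "+"),
      .before = 1)
}

#' @rdname tidy.scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble(scenario = x$scenario$id,
         source = paste(x$scenario$source_cohorts, collapse = "+"),
         target = paste(x$scenario$target_cohorts, collapse = "+"),
         alpha = x$alpha, temperature = x$temperature,
         leakage_free = x$audit$leakage_free,
         best_model = tidy(x)$model[which.max(tidy(x)$accuracy)])
}

#' Ablation sweep over feature-subset sizes and attention
#'
#' For each (subset size, attention flag) cell, restricts all cohorts to the
#' top-`size` F-score SNPs ranked on the pooled source cohorts' training
#' partition (never on target test data), toggles attention in both teacher
#' and student, reruns [run_scenario()] and collects the metric table.
#'
#' @param scenario A [transfer_scenario()].
#' @param cohorts Named list of cohorts.
#' @param subset_sizes Positive SNP-subset sizes (each `<=` the harmonised
#'   panel size).
#' @param attention_flags Logical vector of attention settings to sweep.
#' @param seed Master seed.
#' @param ... Passed to [run_scenario()].
#' @return A tidy tibble: one row per (size, attention, model) with the
#'   metric columns of [tidy.scenario_result()].
#' @export
run_ablation <- function(scenario, cohorts, subset_sizes,
                         attention_flags = c(TRUE, FALSE), seed = 1L, ...) {
  assert_that(all(subset_sizes >= 1), "subset sizes must be positive")
  needed <- c(scenario$source_cohorts, scenario$target_cohorts)
  harmonised <- setNames(harmonise_cohorts(cohorts[needed]), needed)
  p <- length(harmonised[[1]]$rsids)
  assert_that(all(subset_sizes <= p),
              sprintf("subset sizes must not exceed the %d-SNP panel", p))

  # rank SNPs on the pooled source training partition only
  source <- cohort_rbind(harmonised[scenario$source_cohorts], name = "source")
  src_train <- impute_missing(
    stratified_split(source, 0.2, seed = derive_seed(seed, 1))$train, "mean")
  ranking <- f_score(src_train)
  ranked_rsids <- dplyr::arrange(ranking, .data$rank, .data$rsid)$rsid

  grid <- tidyr::expand_grid(size = as.integer(subset_sizes),
                             attention = attention_flags)
  purrr::pmap_dfr(grid, function(size, attention) {
    keep <- sort(match(head(ranked_rsids, size), harmonised[[1]]$rsids))
    reduced <- lapply(harmonised, cohort_subset, cols = keep)
    res <- run_scenario(scenario, reduced, seed = seed,
                        teacher_opts = list(use_attention = attention),
                        ...)
    dplyr::mutate(tidy(res), size = size, attention = attention, .before = 1)
  })
}
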