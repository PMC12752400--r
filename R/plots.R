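#' Plot a feature ranking as a Manhattan-style scan
#'
#' Scores (e.g. `-log10` association p-values) against SNP panel position.
#' Chromosome/base-pair coordinates can be supplied for a genomic x axis.
#'
#' @param object A `feature_ranking` tibble.
#' @param positions Optional tibble with `rsid`, `chrom`, `pos` columns.
#' @param highlight Optional rsIDs drawn in a distinct colour (e.g. planted
#'   causal SNPs).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_ranking <- function(object, positions = NULL,
                                     highlight = NULL, ...) {
  method <- attr(object, "method") %||% "score"
  df <- dplyr::mutate(object, index = match(.data$rsid, .data$rsid))
  df <- df[order(match(df$rsid, sort(df$rsid))), ]
  df$index <- seq_len(nrow(df))
  xlab <- "SNP panel position"
  if (!is.null(positions)) {
    df <- dplyr::inner_join(df, positions, by = "rsid")
    df <- dplyr::arrange(df, .data$chrom, .data$pos)
    df$index <- seq_len(nrow(df))
    xlab <- "genomic order (chrom, pos)"
  }
  df$group <- if (!is.null(highlight)) {
    ifelse(df$rsid %in% highlight, "highlighted", "background")
  } else "background"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 0.8, show.legend = !is.null(highlight)) +
    ggplot2::scale_colour_manual(values = c(background = "grey35",
                                            highlighted = "firebrick")) +
    ggplot2::labs(x = xlab, y = method, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a top-list overlap curve
#'
#' @param object An `overlap_curve` tibble from [overlap_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$overlap)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "top-k threshold", y = "shared SNPs") +
    ggplot2::theme_minimal()
}

#' Plot training-loss history
#'
#' @param object A `training_history` tibble attached to a trained model.
#' @param ... Unused.
#' @return A ggplot object with one line per loss component.
#' @export
autoplot.training_history <- function(object, ...) {
  value_cols <- intersect(c("train_loss", "loss_ce", "loss_distill", "val_loss"),
                          names(object))
  long <- tidyr::pivot_longer(object, dplyr::all_of(value_cols),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ROC curve of an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%s (AUC = %s)", object$model_name,
                      ifelse(is.na(object$auc), "NA",
                             sprintf("%.3f", object$auc)))) +
    ggplot2::theme_minimal()
}

#' Plot top SNP attributions
#'
#' @param object An `attribution_summary`.
#' @param k Number of top SNPs shown.
#' @param ... Unused.
#' @return A ggplot bar chart of mean absolute Shapley values.
#' @export
autoplot.attribution_summary <- function(object, k = 20, ...) {
  df <- head(tidy(object), min(k, length(object$rsids)))
  df$rsid <- factor(df$rsid, levels = rev(df$rsid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_abs_shap, y = .data$rsid)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL,
                  title = sprintf("top SNP impact, cohort %s", object$cohort)) +
    ggplot2::theme_minimal()
}

#' Model tidiers for Wide-Deep models
#'
#' @param x A `wdnn_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter block with its dimensions and
#'   size. `glance()`: a one-row configuration and size summary.
#' @export
tidy.wdnn_model <- function(x, ...) {
  flat <- rapply(x$params, length, how = "unlist")
  tibble(block = names(flat), n_parameters = as.integer(flat))
}

#' @rdname tidy.wdnn_model
#' @export
glance.wdnn_model <- function(x, ...) {
  cfg <- x$config
  tibble(n_snps = cfg$n_snps, embedding_dim = cfg$embedding_dim,
         hidden_layers = length(cfg$hidden_sizes),
         use_attention = cfg$use_attention, n_heads = cfg$n_heads,
         key_dim = cfg$key_dim, activation = cfg$activation,
         n_parameters = x$n_params,
         trained = !is.null(x$history))
}
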