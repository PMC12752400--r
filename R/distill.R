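#' Knowledge-distillation configuration
#'
#' @param temperature Softmax temperature `T > 0` used to soften teacher and
#'   student class distributions. Larger values expose more of the teacher's
#'   dark knowledge (inter-class similarity).
#' @param alpha Mixing weight in [0, 1] on the hard-label cross-entropy;
#'   `1 - alpha` weighs the distillation term.
#' @param alpha_grid Candidate alphas within [0.1, 1.0] for validation-based
#'   tuning; a single value disables tuning.
#' @param epochs,batch_size,learning_rate Student optimiser settings.
#' @param seed Integer seed for student initialisation and shuffling.
#' @return A `distill_config` object.
#' @export
distill_config <- function(temperature = 4, alpha = 0.5, alpha_grid = alpha,
                           epochs = 30, batch_size = 64, learning_rate = 0.01,
                           seed = 1L) {
  assert_that(temperature > 0, "temperature must be positive")
  assert_that(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  assert_that(length(alpha_grid) >= 1 && all(alpha_grid >= 0.1 & alpha_grid <= 1),
              "alpha_grid must be a non-empty subset of [0.1, 1.0]")
  structure(
    list(temperature = temperature, alpha = alpha,
         alpha_grid = as.numeric(alpha_grid),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "distill_config")
}

#' Temperature-scaled softmax
#'
#' `p_i = exp(z_i / T) / sum_j exp(z_j / T)`, computed with max-subtraction
#' for overflow safety. Invariant to adding a constant to all logits; as `T`
#' grows the distribution approaches uniform.
#'
#' @param z Logit vector, or matrix with one logit row per sample.
#' @param temperature Positive temperature `T`.
#' @return Probability vector (or row-stochastic matrix) matching `z`.
#' @export
#' @examples
#' temperature_softmax(c(2, 0), temperature = 2)  # equals softmax of (1, 0)
temperature_softmax <- function(z, temperature = 1) {
  if (temperature <= 0) abort("temperature must be positive")
  if (any(!is.finite(z))) abort("logits must be finite")
  if (is.matrix(z)) return(row_softmax(z / temperature))
  zt <- z / temperature
  e <- exp(zt - max(zt))
  e / sum(e)
}

as_prob_matrix <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  x
}

#' Distillation loss (soft-target cross-entropy)
#'
#' Mean over samples of `-sum_i p_i^(teacher) log p_i^(student)`, the
#' cross-entropy of the student's softened class distribution under the
#' teacher's. Logs are clamped at 1e-12.
#'
#' @param teacher_probs,student_probs Row-stochastic matrices (samples x
#'   classes) of matching shape.
#' @return Non-negative scalar.
#' @export
distillation_loss <- function(teacher_probs, student_probs) {
  tp <- as_prob_matrix(teacher_probs)
  sp <- as_prob_matrix(student_probs)
  if (!all(dim(tp) == dim(sp))) abort("probability matrices must match in shape")
  mean(-rowSums(tp * log(pmax(sp, 1e-12))))
}

#' Combined distillation objective
#'
#' `alpha * L_CE + (1 - alpha) * L_distill`, where `L_CE` is the hard-label
#' cross-entropy of the student's temperature-1 distribution and `L_distill`
#' compares teacher and student distributions softened at the configured
#' temperature. No additional temperature-squared rescaling is applied to
#' the distillation term.
#'
#' @param labels 0/1 labels.
#' @param student_logits,teacher_logits n x 2 class-logit matrices (the
#'   Wide-Deep convention is `(0, fused logit)`).
#' @param config A [distill_config()].
#' @return List with `total`, `ce` and `distill` components.
#' @export
combined_loss <- function(labels, student_logits, teacher_logits, config) {
  if (config$alpha < 0 || config$alpha > 1) abort("alpha must lie in [0, 1]")
  sl <- as_prob_matrix(student_logits)
  tl <- as_prob_matrix(teacher_logits)
  p_hard <- temperature_softmax(sl, 1)
  onehot <- cbind(1 - labels, labels)
  ce <- mean(-rowSums(onehot * log(pmax(p_hard, 1e-12))))
  dist <- distillation_loss(temperature_softmax(tl, config$temperature),
                            temperature_softmax(sl, config$temperature))
  list(total = config$alpha * ce + (1 - config$alpha) * dist,
       ce = ce, distill = dist)
}

#' Distil a student model from a trained teacher
#'
#' Optimises the combined objective of [combined_loss()] on the target
#' cohort's training split: hard labels come from the target data, soft
#' targets from the source-trained teacher's inference-mode logits. The
#' returned history records both loss components per epoch along with the
#' validation F1 used for early stopping and alpha tuning.
#'
#' @param teacher A trained teacher `wdnn_model`.
#' @param student An initialised student `wdnn_model` (e.g. from
#'   [build_student()]) over the same SNP panel.
#' @param target_train,target_val Target-cohort training and validation
#'   [cohort_dataset()]s (imputed).
#' @param config A [distill_config()].
#' @param patience Early-stopping patience on validation loss.
#' @return The trained student, with `history` columns `epoch`,
#'   `train_loss`, `loss_ce`, `loss_distill`, `val_loss` and `val_f1`.
#' @export
train_student <- function(teacher, student, target_train, target_val = NULL,
                          config = distill_config(), patience = 10) {
  assert_that(inherits(config, "distill_config"), "config must be a distill_config")
  if (teacher$config$n_snps != student$config$n_snps) {
    abort("teacher and student feature spaces differ")
  }
  Xtr <- target_train$genotypes
  ytr <- target_train$labels
  zt_tr <- wdnn_forward(teacher, Xtr)$logit
  Tt <- config$temperature
  a <- config$alpha

  # gradient of the combined objective wrt the fused student logit z:
  #   alpha (sigmoid(z) - y) + (1 - alpha) (sigmoid(z/T) - sigmoid(zt/T)) / T
  loss_grad_fn <- function(z, idx) {
    y <- ytr[idx]
    ps <- sigmoid(z)
    ps_T <- sigmoid(z / Tt)
    pt_T <- sigmoid(zt_tr[idx] / Tt)
    ce <- mean(-y * log(pmax(ps, 1e-12)) - (1 - y) * log(pmax(1 - ps, 1e-12)))
    dist <- mean(-pt_T * log(pmax(ps_T, 1e-12)) -
                   (1 - pt_T) * log(pmax(1 - ps_T, 1e-12)))
    dz <- (a * (ps - y) + (1 - a) * (ps_T - pt_T) / Tt) / length(z)
    list(loss = a * ce + (1 - a) * dist, dz = dz,
         loss_ce = ce, loss_distill = dist)
  }

  val_loss_fn <- NULL
  Xval <- NULL; yval <- NULL
  if (!is.null(target_val)) {
    Xval <- target_val$genotypes
    yval <- target_val$labels
    zt_val <- wdnn_forward(teacher, Xval)$logit
    pt_val <- sigmoid(zt_val / Tt)
    val_loss_fn <- function(z) {
      ps <- sigmoid(z); ps_T <- sigmoid(z / Tt)
      ce <- mean(-yval * log(pmax(ps, 1e-12)) -
                   (1 - yval) * log(pmax(1 - ps, 1e-12)))
      dist <- mean(-pt_val * log(pmax(ps_T, 1e-12)) -
                     (1 - pt_val) * log(pmax(1 - ps_T, 1e-12)))
      a * ce + (1 - a) * dist
    }
  }

  fit <- train_wdnn(student, Xtr, ytr, X_val = Xval, y_val = yval,
                    epochs = config$epochs, batch_size = config$batch_size,
                    learning_rate = config$learning_rate, patience = patience,
                    seed = config$seed,
                    loss_grad_fn = loss_grad_fn, val_loss_fn = val_loss_fn)
  if (!is.null(Xval) && nrow(fit$history) > 0) {
    # per-epoch F1 would need stored weights; record the restored model's
    # validation F1 on the final row
    fit$history$val_f1 <- NA_real_
    pred <- as.integer(wdnn_forward(fit, Xval)$probabilities >= 0.5)
    fit$history$val_f1[nrow(fit$history)] <- macro_f1(yval, pred)
  }
  fit
}

#' Tune the distillation mixing weight on validation F1
#'
#' Trains one student per grid alpha (identical seed and initialisation) and
#' returns the alpha with the best validation F1; ties favour the smaller
#' alpha (more distillation).
#'
#' @param teacher Trained teacher.
#' @param student_template Initialised student model used as the common
#'   starting point.
#' @param train,val Target-cohort training and validation splits.
#' @param config A [distill_config()] whose `alpha_grid` is scanned.
#' @return List with `best_alpha`, `scores` (tibble of alpha and
#'   validation F1) and `best_student`.
#' @export
tune_alpha <- function(teacher, student_template, train, val,
                       config = distill_config(alpha_grid = seq(0.1, 1, 0.1))) {
  grid <- config$alpha_grid
  if (length(grid) == 0) abort("alpha_grid must be non-empty")
  fits <- vector("list", length(grid))
  f1s <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg_i <- config
    cfg_i$alpha <- grid[i]
    fits[[i]] <- train_student(teacher, student_template, train, val,
                               config = cfg_i)
    pred <- as.integer(
      wdnn_forward(fits[[i]], val$genotypes)$probabilities >= 0.5)
    f1s[i] <- macro_f1(val$labels, pred)
  }
  ord <- order(-f1s, grid)   # ties -> smaller alpha
  best <- ord[1]
  list(best_alpha = grid[best],
       scores = tibble(alpha = grid, val_f1 = f1s),
       best_student = fits[[best]])
}
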