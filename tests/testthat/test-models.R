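test_that("wide path computes w'[x, phi(x)] + b", {
  # zero weights: bias only
  w0 <- list(w = numeric(3), b = 0.5, cross_pairs = rbind(c(1, 2)),
             include_raw = TRUE)
  expect_equal(wide_forward(c(3, -1), w0), 0.5)

  # hand arithmetic: x = (1, 2), pair (1, 2), unit weights -> 1 + 2 + 2 = 5
  w1 <- list(w = c(1, 1, 1), b = 0, cross_pairs = rbind(c(1, 2)),
             include_raw = TRUE)
  expect_equal(wide_forward(c(1, 2), w1), 5)

  # random case vs an explicit summation oracle
  set.seed(2)
  x <- rnorm(8)
  pairs <- rbind(c(1, 5), c(2, 8), c(3, 4))
  w <- rnorm(8 + 3); b <- rnorm(1)
  oracle <- sum(w[1:8] * x) +
    w[9] * x[1] * x[5] + w[10] * x[2] * x[8] + w[11] * x[3] * x[4] + b
  expect_equal(
    wide_forward(x, list(w = w, b = b, cross_pairs = pairs, include_raw = TRUE)),
    oracle, tolerance = 1e-12)

  expect_error(
    wide_forward(c(1, 2), list(w = c(1, 1, 1), b = 0,
                               cross_pairs = rbind(c(1, 3)), include_raw = TRUE)),
    "out of range")
})

test_that("multi-head attention obeys softmax structure and a hand expansion", {
  set.seed(3)
  d <- 4; dk <- 2; m <- 2
  att <- list(WQ = lapply(1:m, function(i) matrix(rnorm(d * dk), d)),
              WK = lapply(1:m, function(i) matrix(rnorm(d * dk), d)),
              WV = lapply(1:m, function(i) matrix(rnorm(d * dk), d)),
              WO = matrix(rnorm(m * dk * d), m * dk, d),
              key_dim = dk)

  # single token: weight is the softmax of a singleton = 1, so the output is
  # the value path alone
  x1 <- matrix(rnorm(d), 1)
  out1 <- multi_head_attention(x1, att)
  expect_equal(out1$weights[[1]], matrix(1, 1, 1))
  value_path <- cbind(x1 %*% att$WV[[1]], x1 %*% att$WV[[2]]) %*% att$WO
  expect_equal(out1$output, value_path, tolerance = 1e-12)

  # attention-weight rows always sum to 1
  X <- matrix(rnorm(6 * d), 6)
  outX <- multi_head_attention(X, att)
  for (Wts in outX$weights) {
    expect_equal(rowSums(Wts), rep(1, 6), tolerance = 1e-6)
  }

  # 2 tokens, 1 head, hand-chosen 2x2 projections, fully expanded by hand
  WQ <- matrix(c(1, 0, 0.5, -1), 2); WK <- matrix(c(0, 1, 1, 0), 2)
  WV <- matrix(c(1, 1, 0, 2), 2); WO <- diag(2)
  X2 <- matrix(c(1, 0.5, -0.5, 2), 2)
  Q <- X2 %*% WQ; K <- X2 %*% WK; V <- X2 %*% WV
  A <- Q %*% t(K) / sqrt(2)
  S <- matrix(0, 2, 2)
  for (i in 1:2) {
    e <- exp(A[i, ] - max(A[i, ]))
    S[i, ] <- e / sum(e)
  }
  expected <- (S %*% V) %*% WO
  got <- multi_head_attention(
    X2, list(WQ = list(WQ), WK = list(WK), WV = list(WV), WO = WO, key_dim = 2))
  expect_equal(got$output, expected, tolerance = 1e-10)

  expect_error(multi_head_attention(matrix(1, 2, 3), att), "dimension mismatch")
})

test_that("forward pass honours range, zero-weight and logit-pair contracts", {
  cfg <- wdnn_config(n_snps = 10, embedding_dim = 6, hidden_sizes = c(8, 4),
                     n_heads = 2, key_dim = 3,
                     cross_pairs = rbind(c(1, 2), c(3, 7)))
  model <- wdnn_init(cfg, seed = 5)
  set.seed(6)
  X <- matrix(rbinom(8 * 10, 2, 0.3), 8, 10)
  out <- teacher_forward(model, X)
  expect_true(all(out$probabilities > 0 & out$probabilities < 1))
  expect_true(all(is.finite(out$logits)))
  expect_equal(out$logits[, 1], rep(0, 8))

  # softmax over the logit pair at T = 1 equals the sigmoid output
  sm <- t(apply(out$logits, 1, function(z) exp(z) / sum(exp(z))))
  expect_equal(sm[, 2], out$probabilities, tolerance = 1e-6)

  # all weights zero: probability exactly 0.5
  zero <- model
  zero$params <- unpack_params(numeric(length(pack_params(model$params))),
                               model$params)
  expect_equal(teacher_forward(zero, X)$probabilities, rep(0.5, 8))

  # sample-permutation equivariance
  perm <- sample(8)
  expect_equal(teacher_forward(model, X[perm, ])$probabilities,
               out$probabilities[perm])

  expect_error(teacher_forward(model, X[, 1:7]), "expects 10")
})

test_that("attention-free forward equals an independent Wide-Deep oracle", {
  cfg_att <- wdnn_config(n_snps = 12, embedding_dim = 4, hidden_sizes = 6,
                         n_heads = 2, key_dim = 2, use_attention = TRUE,
                         activation = "relu")
  cfg_plain <- wdnn_config(n_snps = 12, embedding_dim = 4, hidden_sizes = 6,
                           use_attention = FALSE, activation = "relu")
  m_att <- wdnn_init(cfg_att, seed = 7)
  m_plain <- wdnn_init(cfg_plain, seed = 7)
  expect_gt(m_att$n_params, m_plain$n_params)

  # oracle: from-scratch reimplementation of the no-attention path
  set.seed(8)
  X <- matrix(rbinom(5 * 12, 2, 0.4), 5, 12)
  pr <- m_plain$params
  pooled <- (X %*% pr$E) / 12 + matrix(colMeans(pr$B), 5, 4, byrow = TRUE)
  h <- pmax(sweep(pooled %*% pr$W[[1]], 2, pr$b[[1]], `+`), 0)
  zw <- as.numeric(X %*% pr$w_wide + pr$b_wide)
  z <- as.numeric(cbind(h, zw) %*% pr$w_out + pr$b_out)
  expect_equal(teacher_forward(m_plain, X)$logit, z, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  for (act in c("relu", "gelu")) {
    cfg <- wdnn_config(n_snps = 6, embedding_dim = 4, hidden_sizes = c(5, 3),
                       activation = act, n_heads = 2, key_dim = 2,
                       cross_pairs = rbind(c(1, 4), c(2, 6)))
    model <- wdnn_init(cfg, seed = 9)
    set.seed(10)
    X <- matrix(rbinom(4 * 6, 2, 0.4) + 0.0, 4, 6)
    y <- c(1, 0, 1, 0)

    loss_at <- function(theta) {
      m2 <- model
      m2$params <- unpack_params(theta, model$params)
      ce_loss_grad(wdnn_forward(m2, X)$logit, y)$loss
    }
    theta <- pack_params(model$params)
    fw <- wdnn_forward(model, X, keep_cache = TRUE)
    analytic <- pack_params(
      wdnn_backward(model, fw$cache, ce_loss_grad(fw$logit, y)$dz))

    h <- 1e-5
    numeric_grad <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (loss_at(tp) - loss_at(tm)) / (2 * h)
    }, numeric(1))
    # relu kinks can sit exactly at 0 for integer dosages; gelu is smooth
    tol <- if (act == "gelu") 1e-6 else 1e-5
    expect_lt(max(abs(analytic - numeric_grad) / (abs(numeric_grad) + 1)), tol)
  }
})

test_that("feature extraction is deterministic with the configured width", {
  cfg <- wdnn_config(n_snps = 8, embedding_dim = 4, hidden_sizes = c(6, 3),
                     n_heads = 1, key_dim = 4)
  model <- wdnn_init(cfg, seed = 11)
  set.seed(12)
  X <- matrix(rbinom(10 * 8, 2, 0.3), 10, 8)
  f1 <- extract_features(model, X)
  f2 <- extract_features(model, X)
  expect_identical(f1, f2)
  # default "fused" = last hidden (width 3) + wide output (1 column)
  expect_equal(dim(f1), c(10, 4))
  expect_equal(dim(extract_features(model, X, "hidden2")), c(10, 3))
  expect_equal(dim(extract_features(model, X, "hidden1")), c(10, 6))
  expect_equal(dim(extract_features(model, X, "pooled")), c(10, 4))

  zero <- model
  zero$params <- unpack_params(numeric(length(pack_params(model$params))),
                               model$params)
  expect_true(all(extract_features(zero, X) == 0))  # zero affine maps throughout

  expect_error(extract_features(model, X, "hidden9"), "fused, pooled, hidden1")
})

test_that("student construction enforces strictly fewer parameters", {
  tc <- wdnn_config(n_snps = 20, embedding_dim = 8, hidden_sizes = c(64, 32),
                    n_heads = 2, key_dim = 4)
  teacher <- wdnn_init(tc, seed = 1)
  student <- build_student(tc, reduction = list(heads = 0.5, layers = 0.5,
                                                width = 0.5, embed = 0.5))
  expect_lt(student$n_params, teacher$n_params)
  expect_equal(student$config$n_heads, 1L)
  expect_length(student$config$hidden_sizes, 1L)

  expect_error(build_student(tc, reduction = list(heads = 1, layers = 1,
                                                  width = 1, embed = 1)),
               "not strictly smaller")
  expect_error(build_student(tc, reduction = list(width = 1.5)), "\\(0, 1]")
})

test_that("training reduces loss and is seed-deterministic", {
  sim <- small_sim(n_cohorts = 1, n = 300, p = 20, n_causal = 4, beta = 1,
                   seed = 13)
  d <- sim$cohorts[[1]]
  cfg <- wdnn_config(n_snps = 20, embedding_dim = 4, hidden_sizes = 8,
                     n_heads = 1, key_dim = 4)
  m0 <- wdnn_init(cfg, seed = 14)
  fit <- train_wdnn(m0, d, epochs = 10, batch_size = 64, seed = 15)
  expect_lt(dplyr::last(fit$history$train_loss), fit$history$train_loss[1])

  fit2 <- train_wdnn(m0, d, epochs = 10, batch_size = 64, seed = 15)
  expect_identical(pack_params(fit$params), pack_params(fit2$params))
})

test_that("a teacher on strongly additive signal separates held-out samples", {
  # planted additive signal (beta = 1 at 10 of 75 SNPs, n = 2000); a modest
  # teacher should train to roughly the Bayes limit of the generative model
  res <- vapply(1:3, function(s) {
    sim <- small_sim(n_cohorts = 1, n = 2000, p = 75, n_causal = 10, beta = 1,
                     seed = 400 + s)
    sp <- stratified_split(sim$cohorts[[1]], 0.2, seed = s)
    cfg <- wdnn_config(n_snps = 75, embedding_dim = 8, hidden_sizes = c(32, 16),
                       n_heads = 2, key_dim = 4)
    fit <- train_teacher(cfg, sp$train, epochs = 30, learning_rate = 0.003,
                         seed = s)
    prob <- teacher_forward(fit, sp$test)$probabilities
    bayes <- plogis(sp$test$genotypes[, sim$truth$causal_indices] %*%
                      sim$truth$effect_sizes)
    c(auc = auc_rank(sp$test$labels, prob),
      bayes = auc_rank(sp$test$labels, as.numeric(bayes)))
  }, numeric(2))
  expect_gte(median(res["auc", ]), 0.85)
  # the trained teacher sits close to the true-liability (Bayes) AUC
  expect_gte(median(res["auc", ] - res["bayes", ]), -0.03)
})
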