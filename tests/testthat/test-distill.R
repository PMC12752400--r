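test_that("temperature softmax satisfies its closed forms and stability", {
  for (Tt in c(0.5, 1, 4)) {
    expect_equal(temperature_softmax(c(0, 0), Tt), c(0.5, 0.5))
  }
  # z = (2, 0) at T = 2 equals softmax of (1, 0)
  expect_equal(temperature_softmax(c(2, 0), 2),
               c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))), tolerance = 1e-12)
  # extreme logits: no overflow
  p <- temperature_softmax(c(1000, 0), 1)
  expect_equal(p, c(1, 0))
  expect_true(all(is.finite(p)))

  expect_error(temperature_softmax(c(1, 0), 0), "positive")
  expect_error(temperature_softmax(c(Inf, 0), 1), "finite")
})

test_that("temperature softmax is shift-invariant and entropy grows with T", {
  set.seed(21)
  ent <- function(p) -sum(p * log(p))
  for (i in 1:20) {
    z <- rnorm(4, sd = 3)
    c_shift <- rnorm(1, sd = 10)
    Tt <- runif(1, 0.2, 10)
    expect_equal(temperature_softmax(z, Tt), temperature_softmax(z + c_shift, Tt),
                 tolerance = 1e-12)
    temps <- sort(runif(5, 0.1, 20))
    ents <- vapply(temps, function(tt) ent(temperature_softmax(z, tt)), numeric(1))
    expect_true(all(diff(ents) >= -1e-10))
  }
  # matrix form: rows are handled independently
  Z <- matrix(c(2, 0, 0, 0), 2, 2, byrow = TRUE)
  P <- temperature_softmax(Z, 2)
  expect_equal(P[1, ], temperature_softmax(c(2, 0), 2))
  expect_equal(P[2, ], c(0.5, 0.5))
})

test_that("distillation loss matches entropy limits and a per-element oracle", {
  u <- matrix(0.5, 1, 2)
  expect_equal(distillation_loss(u, u), log(2), tolerance = 1e-12)

  onehot <- matrix(c(0, 1), 1)
  sure <- matrix(c(1e-12, 1), 1)   # argmax probability ~1
  expect_equal(distillation_loss(onehot, sure), 0, tolerance = 1e-10)

  set.seed(22)
  tp <- matrix(runif(32), 16, 2); tp <- tp / rowSums(tp)
  sp <- matrix(runif(32), 16, 2); sp <- sp / rowSums(sp)
  oracle <- 0
  for (i in 1:16) for (j in 1:2) {
    oracle <- oracle - tp[i, j] * log(sp[i, j])
  }
  expect_equal(distillation_loss(tp, sp), oracle / 16, tolerance = 1e-10)

  expect_error(distillation_loss(tp, sp[1:8, ]), "shape")
})

test_that("combined loss degenerates to its components and mixes by hand", {
  set.seed(23)
  labels <- c(1, 0)
  sl <- cbind(0, rnorm(2))
  tl <- cbind(0, rnorm(2))

  cfg1 <- distill_config(temperature = 3, alpha = 1)
  out1 <- combined_loss(labels, sl, tl, cfg1)
  expect_equal(out1$total, out1$ce, tolerance = 1e-12)
  # teacher logits are irrelevant at alpha = 1
  out1b <- combined_loss(labels, sl, tl + 5, cfg1)
  expect_equal(out1$total, out1b$total, tolerance = 1e-12)

  cfg0 <- distill_config(temperature = 3, alpha = 0.1)
  cfg0$alpha <- 0   # grid constraint keeps constructor alphas in [0.1, 1]
  out0 <- combined_loss(labels, sl, tl, cfg0)
  expect_equal(out0$total,
               distillation_loss(temperature_softmax(tl, 3),
                                 temperature_softmax(sl, 3)),
               tolerance = 1e-12)

  # alpha = 0.5: hand sum of the two components
  cfg5 <- distill_config(temperature = 2, alpha = 0.5)
  out5 <- combined_loss(labels, sl, tl, cfg5)
  ce_hand <- mean(-log(c(temperature_softmax(sl, 1)[1, 2],
                         temperature_softmax(sl, 1)[2, 1])))
  d_hand <- distillation_loss(temperature_softmax(tl, 2),
                              temperature_softmax(sl, 2))
  expect_equal(out5$total, 0.5 * ce_hand + 0.5 * d_hand, tolerance = 1e-10)

  # continuity in alpha: |L(a) - L(a')| <= |a - a'| (L_CE + L_dist)
  for (i in 1:10) {
    a1 <- runif(1); a2 <- runif(1)
    c1 <- cfg5; c1$alpha <- a1
    c2 <- cfg5; c2$alpha <- a2
    l1 <- combined_loss(labels, sl, tl, c1)
    l2 <- combined_loss(labels, sl, tl, c2)
    expect_lte(abs(l1$total - l2$total),
               abs(a1 - a2) * (l1$ce + l1$distill) + 1e-12)
  }

  cfg_bad <- cfg5; cfg_bad$alpha <- 1.2
  expect_error(combined_loss(labels, sl, tl, cfg_bad), "alpha")
})

test_that("alpha outside the unit interval is rejected at construction", {
  expect_error(distill_config(alpha = 1.5), "alpha")
  expect_error(distill_config(temperature = -1), "temperature")
  expect_error(distill_config(alpha_grid = c(0.05, 0.5)), "alpha_grid")
})

make_distill_fixture <- function(seed = 30, n = 300, p = 20) {
  sim <- small_sim(n_cohorts = 2, n = n, p = p, n_causal = 4, beta = 1,
                   shift_sd = 0.1, seed = seed)
  src <- sim$cohorts[[1]]; tgt <- sim$cohorts[[2]]
  cfg <- wdnn_config(n_snps = p, embedding_dim = 4, hidden_sizes = c(16, 8),
                     n_heads = 2, key_dim = 2)
  teacher <- train_teacher(cfg, src, epochs = 15, seed = seed)
  sp <- stratified_split(tgt, 0.25, seed = seed)
  list(teacher = teacher, cfg = cfg, train = sp$train, val = sp$test)
}

test_that("student training honours the zero-epoch and uniform-T limits", {
  fx <- make_distill_fixture()
  student0 <- build_student(fx$cfg, seed = 31)

  # 0 epochs: unchanged parameters
  out0 <- train_student(fx$teacher, student0, fx$train, fx$val,
                        config = distill_config(epochs = 0))
  expect_identical(gwaskd:::pack_params(out0$params),
                   gwaskd:::pack_params(student0$params))

  # very large T: soft targets are uniform, distillation component ~ ln 2
  outT <- train_student(fx$teacher, student0, fx$train, fx$val,
                        config = distill_config(temperature = 1e6, epochs = 1,
                                                seed = 32))
  expect_lt(abs(outT$history$loss_distill[1] - log(2)), 1e-3)

  # mismatched panels are rejected
  shrunk <- build_student(wdnn_config(n_snps = 10, embedding_dim = 4,
                                      hidden_sizes = c(16, 8), n_heads = 2,
                                      key_dim = 2), seed = 1)
  expect_error(train_student(fx$teacher, shrunk, fx$train), "feature spaces")
})

test_that("the distillation component decreases over early epochs", {
  fx <- make_distill_fixture(seed = 33)
  student0 <- build_student(fx$cfg, seed = 34)
  fit <- train_student(fx$teacher, student0, fx$train, fx$val,
                       config = distill_config(alpha = 0.5, epochs = 8,
                                               learning_rate = 0.005,
                                               seed = 35))
  first5 <- fit$history$loss_distill[1:5]
  expect_true(all(diff(first5) < 0))
  expect_true(all(c("loss_ce", "loss_distill", "val_loss") %in%
                    names(fit$history)))
})

test_that("alpha tuning returns the grid argmax with ties toward distillation", {
  fx <- make_distill_fixture(seed = 36)
  student0 <- build_student(fx$cfg, seed = 37)

  one <- tune_alpha(fx$teacher, student0, fx$train, fx$val,
                    config = distill_config(alpha_grid = 0.4, epochs = 3,
                                            seed = 38))
  expect_equal(one$best_alpha, 0.4)

  two <- tune_alpha(fx$teacher, student0, fx$train, fx$val,
                    config = distill_config(alpha_grid = c(0.3, 0.7),
                                            epochs = 3, seed = 38))
  expect_equal(nrow(two$scores), 2)
  expect_true(two$best_alpha %in% c(0.3, 0.7))
  expect_equal(two$best_alpha, two$scores$alpha[which.max(two$scores$val_f1)])
})

test_that("distillation helps when the teacher knows the target's model", {
  # teacher trained on the target's own generative distribution: mixing in
  # its soft targets should beat pure hard-label training (alpha < 1) in
  # most seeds
  hits <- vapply(1:10, function(s) {
    sim <- small_sim(n_cohorts = 2, n = 250, p = 20, n_causal = 4, beta = 1,
                     shift_sd = 0, seed = 500 + s)
    cfg <- wdnn_config(n_snps = 20, embedding_dim = 4, hidden_sizes = 8,
                       n_heads = 1, key_dim = 4)
    teacher <- train_teacher(cfg, sim$cohorts[[1]], epochs = 12, seed = s)
    sp <- stratified_split(sim$cohorts[[2]], 0.3, seed = s)
    student0 <- build_student(cfg, reduction = list(width = 0.5, embed = 0.75),
                              seed = s)
    res <- tune_alpha(teacher, student0, sp$train, sp$test,
                      config = distill_config(alpha_grid = c(0.2, 0.5, 1.0),
                                              epochs = 10, seed = s))
    res$best_alpha < 1
  }, logical(1))
  expect_gte(sum(hits), 7)
})
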