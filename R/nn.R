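#' Wide-Deep network configuration
#'
#' Describes a Wide-Deep classifier over SNP dosages. The wide path is a
#' linear map over the raw dosage vector and configured cross-product
#' features; the deep path embeds each SNP's scalar dosage into a learned
#' `embedding_dim`-wide token, optionally mixes tokens with multi-head
#' self-attention, average-pools over SNPs and applies dense hidden layers.
#' The two paths are fused by an affine map over the concatenation of the
#' last hidden activation and the wide output, giving a single logit; the
#' class-logit pair is `(0, logit)` so that a temperature-1 softmax over the
#' pair equals the sigmoid probability.
#'
#' @param n_snps Number of SNP input features.
#' @param embedding_dim Per-SNP token width of the deep path.
#' @param hidden_sizes Integer vector of dense hidden-layer widths (>= 1
#'   layer).
#' @param activation `"gelu"` (default; smooth, avoids dead-unit collapse of
#'   small hidden layers) or `"relu"`.
#' @param dropout_rate Dropout fraction in [0, 1) applied to hidden
#'   activations during training.
#' @param use_attention Whether the deep path applies multi-head
#'   self-attention over SNP tokens.
#' @param n_heads Number of attention heads.
#' @param key_dim Per-head query/key/value width.
#' @param cross_pairs Two-column integer matrix of SNP index pairs whose
#'   dosage products feed the wide path, or `NULL` for none.
#' @param include_raw Whether raw dosages feed the wide path alongside the
#'   cross products.
#' @return A `wdnn_config` object.
#' @seealso [wdnn_init()], [teacher_config()], [build_student()]
#' @export
wdnn_config <- function(n_snps, embedding_dim = 16, hidden_sizes = c(128, 64),
                        activation = c("gelu", "relu"), dropout_rate = 0,
                        use_attention = TRUE, n_heads = 4,
                        key_dim = max(1L, embedding_dim %/% max(1L, n_heads)),
                        cross_pairs = NULL, include_raw = TRUE) {
  activation <- match.arg(activation)
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  assert_that(embedding_dim >= 1, "embedding_dim must be >= 1")
  assert_that(length(hidden_sizes) >= 1 && all(hidden_sizes >= 1),
              "at least one hidden layer of positive width is required")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must lie in [0, 1)")
  if (use_attention) {
    assert_that(n_heads >= 1 && key_dim >= 1,
                "n_heads and key_dim must be positive")
  }
  if (!is.null(cross_pairs)) {
    cross_pairs <- matrix(as.integer(cross_pairs), ncol = 2)
    assert_that(all(cross_pairs >= 1 & cross_pairs <= n_snps),
                "cross-product indices must be valid SNP indices")
    assert_that(all(cross_pairs[, 1] != cross_pairs[, 2]),
                "cross-product pair indices must be distinct within a pair")
  }
  structure(
    list(n_snps = as.integer(n_snps),
         embedding_dim = as.integer(embedding_dim),
         hidden_sizes = as.integer(hidden_sizes),
         activation = activation,
         dropout_rate = dropout_rate,
         use_attention = isTRUE(use_attention),
         n_heads = as.integer(n_heads),
         key_dim = as.integer(key_dim),
         cross_pairs = cross_pairs,
         include_raw = isTRUE(include_raw)),
    class = "wdnn_config")
}

#' Teacher and student default configurations
#'
#' `teacher_config()` is the high-capacity Wide-Deep default (embedding 16,
#' 4 attention heads, hidden layers 128-64); `student_config()` is the
#' lightweight counterpart (embedding 8, 1 head, one 32-wide hidden layer).
#'
#' @inheritParams wdnn_config
#' @param ... Overrides passed to [wdnn_config()].
#' @return A `wdnn_config`.
#' @export
teacher_config <- function(n_snps, cross_pairs = NULL, ...) {
  args <- utils::modifyList(
    list(n_snps = n_snps, embedding_dim = 16, hidden_sizes = c(128, 64),
         n_heads = 4, cross_pairs = cross_pairs),
    list(...))
  if (!"key_dim" %in% names(list(...))) {
    args$key_dim <- max(1L, args$embedding_dim %/% max(1L, args$n_heads))
  }
  do.call(wdnn_config, args)
}

#' @rdname teacher_config
#' @export
student_config <- function(n_snps, cross_pairs = NULL, ...) {
  args <- utils::modifyList(
    list(n_snps = n_snps, embedding_dim = 8, hidden_sizes = 32,
         n_heads = 1, cross_pairs = cross_pairs),
    list(...))
  if (!"key_dim" %in% names(list(...))) {
    args$key_dim <- max(1L, args$embedding_dim %/% max(1L, args$n_heads))
  }
  do.call(wdnn_config, args)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialise a Wide-Deep model
#'
#' Draws Glorot-uniform weights (zero biases) for every component of a
#' [wdnn_config()]. Deterministic given `seed`.
#'
#' @param config A `wdnn_config`.
#' @param seed Integer seed controlling initialisation.
#' @return A `wdnn_model`: list with `config`, `params` and `n_params`.
#' @export
wdnn_init <- function(config, seed = 1L) {
  assert_that(inherits(config, "wdnn_config"), "config must be a wdnn_config")
  withr::local_seed(seed)
  p <- config$n_snps
  d <- config$embedding_dim
  n_pairs <- if (is.null(config$cross_pairs)) 0L else nrow(config$cross_pairs)
  p_wide <- n_pairs + if (config$include_raw) p else 0L

  params <- list(
    w_wide = as.numeric(glorot(max(p_wide, 1), 1))[seq_len(p_wide)],
    b_wide = 0,
    E = glorot(p, d),
    B = matrix(0, p, d))
  if (config$use_attention) {
    dk <- config$key_dim
    params$WQ <- lapply(seq_len(config$n_heads), function(i) glorot(d, dk))
    params$WK <- lapply(seq_len(config$n_heads), function(i) glorot(d, dk))
    params$WV <- lapply(seq_len(config$n_heads), function(i) glorot(d, dk))
    params$WO <- glorot(config$n_heads * dk, d)
  }
  sizes <- c(d, config$hidden_sizes)
  params$W <- lapply(seq_along(config$hidden_sizes),
                     function(l) glorot(sizes[l], sizes[l + 1]))
  params$b <- lapply(config$hidden_sizes, function(h) numeric(h))
  params$w_out <- as.numeric(glorot(utils::tail(config$hidden_sizes, 1) + 1, 1))
  params$b_out <- 0

  model <- structure(list(config = config, params = params), class = "wdnn_model")
  model$n_params <- n_params(model)
  model
}

#' Trainable parameter count
#'
#' @param model A `wdnn_model` (or its `params` list).
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  params <- if (inherits(model, "wdnn_model")) model$params else model
  sum(vapply(rapply(params, length, how = "unlist"), identity, numeric(1)))
}

#' @export
print.wdnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<wdnn_model: %d SNPs, embed %d, hidden [%s], %s, %d parameters>\n",
    cfg$n_snps, cfg$embedding_dim, paste(cfg$hidden_sizes, collapse = ", "),
    if (cfg$use_attention) sprintf("%d-head attention (d_k = %d)",
                                   cfg$n_heads, cfg$key_dim) else "no attention",
    x$n_params))
  invisible(x)
}

# ---- parameter packing (flat vector <-> structured list) -------------------

pack_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unpack_params <- function(vec, template) {
  out <- template
  pos <- 0L
  assign_like <- function(x) {
    if (is.list(x)) return(lapply(x, assign_like))
    n <- length(x)
    if (n == 0L) return(x)
    val <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(val) <- dim(x)
    val
  }
  out <- assign_like(template)
  stopifnot(pos == length(vec))
  out
}

# ---- activations ------------------------------------------------------------

act_fun <- function(z, kind) {
  switch(kind, relu = pmax(z, 0), gelu = z * pnorm(z))
}
act_grad <- function(z, kind) {
  switch(kind, relu = (z > 0) * 1, gelu = pnorm(z) + z * stats::dnorm(z))
}

#' Wide-path output for a single dosage vector
#'
#' Computes the wide component `w' [x, phi(x)] + b`, where `phi(x)`
#' concatenates the dosage products `x_a * x_b` of the configured
#' cross-product pairs.
#'
#' @param x Numeric dosage vector.
#' @param wide List with `w` (weights over raw + cross features), `b`
#'   (scalar bias), `cross_pairs` (two-column index matrix or `NULL`) and
#'   `include_raw` flag.
#' @return A single numeric value.
#' @export
#' @examples
#' wide_forward(c(1, 2), list(w = c(1, 1, 1), b = 0,
#'                            cross_pairs = rbind(c(1, 2)), include_raw = TRUE))
wide_forward <- function(x, wide) {
  pairs <- wide$cross_pairs
  if (!is.null(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (any(pairs < 1 | pairs > length(x))) {
      abort("cross-product index out of range")
    }
  }
  include_raw <- wide$include_raw %||% TRUE
  feats <- c(if (include_raw) x,
             if (!is.null(pairs)) x[pairs[, 1]] * x[pairs[, 2]])
  if (length(feats) == 0) return(wide$b)
  assert_that(length(wide$w) == length(feats),
              "wide weight length must match raw + cross feature count")
  sum(wide$w * feats) + wide$b
}

# batch wide features: n x p_wide
wide_features <- function(X, config) {
  feats <- NULL
  if (config$include_raw) feats <- X
  if (!is.null(config$cross_pairs)) {
    ph <- X[, config$cross_pairs[, 1], drop = FALSE] *
      X[, config$cross_pairs[, 2], drop = FALSE]
    feats <- if (is.null(feats)) ph else cbind(feats, ph)
  }
  feats
}

row_softmax <- function(A) {
  # max-subtraction for overflow safety; max.col is much faster than apply
  mx <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  E <- exp(A - mx)
  E / rowSums(E)
}

#' Multi-head self-attention over a token matrix
#'
#' Scaled dot-product self-attention: per head `i`,
#' `softmax(X W_Q^i (X W_K^i)' / sqrt(d_k)) X W_V^i`; head outputs are
#' concatenated and projected by `W_O`. Attention-weight rows sum to one.
#'
#' @param X Token matrix (tokens x model width).
#' @param attention List with `WQ`, `WK`, `WV` (lists of d x d_k matrices,
#'   one per head), `WO` ((heads * d_k) x d_out), and `key_dim`.
#' @return List with `output` (tokens x d_out) and `weights` (list of
#'   per-head attention matrices).
#' @export
multi_head_attention <- function(X, attention) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 1, "need at least one token row")
  dk <- attention$key_dim %||% ncol(attention$WQ[[1]])
  m <- length(attention$WQ)
  for (nm in c("WQ", "WK", "WV")) {
    for (Wm in attention[[nm]]) {
      if (nrow(Wm) != ncol(X)) abort("attention projection dimension mismatch")
    }
  }
  heads <- vector("list", m)
  weights <- vector("list", m)
  for (i in seq_len(m)) {
    Q <- X %*% attention$WQ[[i]]
    K <- X %*% attention$WK[[i]]
    V <- X %*% attention$WV[[i]]
    S <- row_softmax(Q %*% t(K) / sqrt(dk))
    weights[[i]] <- S
    heads[[i]] <- S %*% V
  }
  C <- do.call(cbind, heads)
  if (ncol(C) != nrow(attention$WO)) abort("W_O dimension mismatch")
  list(output = C %*% attention$WO, weights = weights)
}

# Batched MHA over all samples of a minibatch. Tokens of every sample are
# stacked sample-major into one (n * p) x d matrix so the Q/K/V/O projections
# are single large matmuls; only the p x p attention softmax stays per
# sample. `groups` maps stacked rows to samples.
mha_forward_batch <- function(T_all, params, n, p, n_heads, dk) {
  heads_S <- vector("list", n_heads)
  C_all <- matrix(0, n * p, n_heads * dk)
  QKV <- vector("list", n_heads)
  for (i in seq_len(n_heads)) {
    Q <- T_all %*% params$WQ[[i]]
    K <- T_all %*% params$WK[[i]]
    V <- T_all %*% params$WV[[i]]
    QKV[[i]] <- list(Q = Q, K = K, V = V)
    S_list <- vector("list", n)
    cols <- ((i - 1) * dk + 1):(i * dk)
    for (s in seq_len(n)) {
      rows <- ((s - 1) * p + 1):(s * p)
      S <- row_softmax(Q[rows, , drop = FALSE] %*%
                         t(K[rows, , drop = FALSE]) / sqrt(dk))
      S_list[[s]] <- S
      C_all[rows, cols] <- S %*% V[rows, , drop = FALSE]
    }
    heads_S[[i]] <- S_list
  }
  list(O = C_all %*% params$WO, C = C_all, S = heads_S, QKV = QKV)
}

mha_backward_batch <- function(dO_all, fwd, T_all, params, n, p, n_heads, dk,
                               grads) {
  dC <- dO_all %*% t(params$WO)
  grads$WO <- grads$WO + crossprod(fwd$C, dO_all)
  dT <- matrix(0, n * p, ncol(T_all))
  for (i in seq_len(n_heads)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    qkv <- fwd$QKV[[i]]
    dQ <- matrix(0, n * p, dk)
    dK <- matrix(0, n * p, dk)
    dV <- matrix(0, n * p, dk)
    for (s in seq_len(n)) {
      rows <- ((s - 1) * p + 1):(s * p)
      dH <- dC[rows, cols, drop = FALSE]
      S <- fwd$S[[i]][[s]]
      dS <- dH %*% t(qkv$V[rows, , drop = FALSE])
      dV[rows, ] <- crossprod(S, dH)
      # softmax jacobian, rowwise
      dA <- S * (dS - rowSums(dS * S))
      dQ[rows, ] <- dA %*% qkv$K[rows, , drop = FALSE] / sqrt(dk)
      dK[rows, ] <- crossprod(dA, qkv$Q[rows, , drop = FALSE]) / sqrt(dk)
    }
    grads$WQ[[i]] <- grads$WQ[[i]] + crossprod(T_all, dQ)
    grads$WK[[i]] <- grads$WK[[i]] + crossprod(T_all, dK)
    grads$WV[[i]] <- grads$WV[[i]] + crossprod(T_all, dV)
    dT <- dT + tcrossprod(dQ, params$WQ[[i]]) +
      tcrossprod(dK, params$WK[[i]]) + tcrossprod(dV, params$WV[[i]])
  }
  list(dT = dT, grads = grads)
}

# full forward pass over a batch; returns logits and (optionally) a cache
wdnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  pr <- model$params
  n <- nrow(X); p <- cfg$n_snps
  if (ncol(X) != p) {
    abort(sprintf("SNP count mismatch: model expects %d, input has %d", p, ncol(X)))
  }

  XW <- wide_features(X, cfg)
  z_w <- if (is.null(XW)) rep(pr$b_wide, n) else
    as.numeric(XW %*% pr$w_wide + pr$b_wide)

  if (!cfg$use_attention) {
    pooled <- (X %*% pr$E) / p +
      matrix(colMeans(pr$B), n, cfg$embedding_dim, byrow = TRUE)
    mha_cache <- NULL
    T_all <- NULL
  } else {
    # stack per-sample token matrices sample-major: row (s-1)p + j holds
    # token j of sample s, i.e. x_{sj} E_j + B_j
    jrep <- rep(seq_len(p), n)
    T_all <- pr$E[jrep, , drop = FALSE] * as.vector(t(X)) + pr$B[jrep, , drop = FALSE]
    mha_cache <- mha_forward_batch(T_all, pr, n, p, cfg$n_heads, cfg$key_dim)
    pooled <- rowsum(mha_cache$O, group = rep(seq_len(n), each = p),
                     reorder = FALSE) / p
  }

  L <- length(cfg$hidden_sizes)
  Z <- vector("list", L); A <- vector("list", L)
  drop_masks <- vector("list", L)
  a_prev <- pooled
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(a_prev %*% pr$W[[l]], 2, pr$b[[l]], `+`)
    A[[l]] <- act_fun(Z[[l]], cfg$activation)
    if (training && cfg$dropout_rate > 0) {
      mask <- matrix(runif(length(A[[l]])) >= cfg$dropout_rate,
                     nrow(A[[l]]), ncol(A[[l]])) / (1 - cfg$dropout_rate)
      A[[l]] <- A[[l]] * mask
      drop_masks[[l]] <- mask
    }
    a_prev <- A[[l]]
  }

  fused <- cbind(A[[L]], z_w)
  z <- as.numeric(fused %*% pr$w_out + pr$b_out)

  out <- list(logit = z,
              logits = cbind(0, z),
              probabilities = sigmoid(z))
  if (keep_cache) {
    out$cache <- list(X = X, XW = XW, z_w = z_w, pooled = pooled,
                      mha = mha_cache, T_all = T_all, Z = Z, A = A,
                      drop_masks = drop_masks, fused = fused)
  }
  out
}

# backward pass: dz is dLoss/dlogit per sample (length n, averaging included)
wdnn_backward <- function(model, cache, dz) {
  cfg <- model$config
  pr <- model$params
  n <- length(dz); p <- cfg$n_snps
  L <- length(cfg$hidden_sizes)

  grads <- list(w_wide = numeric(length(pr$w_wide)), b_wide = 0,
                E = matrix(0, p, cfg$embedding_dim),
                B = matrix(0, p, cfg$embedding_dim))
  if (cfg$use_attention) {
    grads$WQ <- lapply(pr$WQ, function(w) w * 0)
    grads$WK <- lapply(pr$WK, function(w) w * 0)
    grads$WV <- lapply(pr$WV, function(w) w * 0)
    grads$WO <- pr$WO * 0
  }
  grads$W <- lapply(pr$W, function(w) w * 0)
  grads$b <- lapply(pr$b, function(bb) bb * 0)

  d_L <- utils::tail(cfg$hidden_sizes, 1)
  grads$w_out <- as.numeric(t(cache$fused) %*% dz)
  grads$b_out <- sum(dz)
  d_fused <- outer(dz, pr$w_out)
  dA <- d_fused[, seq_len(d_L), drop = FALSE]
  dz_w <- d_fused[, d_L + 1]

  if (!is.null(cache$XW)) {
    grads$w_wide <- as.numeric(t(cache$XW) %*% dz_w)
  }
  grads$b_wide <- sum(dz_w)

  for (l in rev(seq_len(L))) {
    if (!is.null(cache$drop_masks[[l]])) dA <- dA * cache$drop_masks[[l]]
    dZ <- dA * act_grad(cache$Z[[l]], cfg$activation)
    a_prev <- if (l == 1) cache$pooled else cache$A[[l - 1]]
    grads$W[[l]] <- t(a_prev) %*% dZ
    grads$b[[l]] <- colSums(dZ)
    dA <- dZ %*% t(pr$W[[l]])
  }
  d_pooled <- dA   # n x embedding_dim

  if (!cfg$use_attention) {
    grads$E <- t(cache$X) %*% d_pooled / p
    grads$B <- matrix(colSums(d_pooled) / p, p, cfg$embedding_dim, byrow = TRUE)
  } else {
    # pooled_s = colMeans of sample s's p output tokens
    dO_all <- d_pooled[rep(seq_len(n), each = p), , drop = FALSE] / p
    bk <- mha_backward_batch(dO_all, cache$mha, cache$T_all, pr, n, p,
                             cfg$n_heads, cfg$key_dim, grads)
    grads <- bk$grads
    jrep <- rep(seq_len(p), n)
    dT_scaled <- bk$dT * as.vector(t(cache$X))
    grads$E <- grads$E + rowsum(dT_scaled, group = jrep, reorder = FALSE)
    grads$B <- grads$B + rowsum(bk$dT, group = jrep, reorder = FALSE)
  }
  grads
}

#' Forward pass of a Wide-Deep model
#'
#' Runs the model in inference mode on a dosage matrix.
#'
#' @param model A trained or initialised `wdnn_model`.
#' @param X Numeric matrix, samples x SNPs (column count must match the
#'   model's configured SNP count) — or a [cohort_dataset()].
#' @return List with `logits` (n x 2 matrix, first column fixed at 0),
#'   `probabilities` (positive-class probability per sample) and `logit`
#'   (the fused scalar logit).
#' @export
teacher_forward <- function(model, X) {
  if (inherits(X, "cohort_dataset")) X <- X$genotypes
  out <- wdnn_forward(model, as.matrix(X), training = FALSE)
  out[c("logits", "probabilities", "logit")]
}

#' Extract hidden-layer activations from a trained model
#'
#' Returns deterministic inference-mode activations of a named layer. The
#' default, `"fused"`, is the model's penultimate representation: the last
#' hidden activation concatenated with the wide-path output — the complete
#' pre-logit feature vector, and the representation handed to downstream
#' classifiers. `"hiddenL"` gives the deep path's last hidden activation
#' alone.
#'
#' @param model A `wdnn_model`.
#' @param X Dosage matrix or [cohort_dataset()].
#' @param layer Layer name: `"fused"`, `"pooled"` or `"hidden1"` ...
#'   `"hiddenL"`.
#' @return Numeric matrix, samples x layer width.
#' @export
extract_features <- function(model, X, layer = NULL) {
  if (inherits(X, "cohort_dataset")) X <- X$genotypes
  L <- length(model$config$hidden_sizes)
  names_avail <- c("fused", "pooled", paste0("hidden", seq_len(L)))
  if (is.null(layer)) layer <- "fused"
  if (!layer %in% names_avail) {
    abort(sprintf("unknown layer '%s'; available: %s", layer,
                  paste(names_avail, collapse = ", ")))
  }
  out <- wdnn_forward(model, as.matrix(X), training = FALSE, keep_cache = TRUE)
  switch(layer,
         fused = out$cache$fused,
         pooled = out$cache$pooled,
         out$cache$A[[as.integer(sub("hidden", "", layer))]])
}

#' Build a reduced student configuration from a teacher's
#'
#' Shrinks attention heads, hidden-layer count and widths, and the embedding
#' by the given factors in (0, 1], then verifies the student has strictly
#' fewer trainable parameters than the teacher.
#'
#' @param teacher_config The teacher's `wdnn_config`.
#' @param reduction Named list of shrink factors in (0, 1]: `heads`,
#'   `layers`, `width`, `embed`.
#' @param seed Seed for the returned initialised student model.
#' @return An initialised student `wdnn_model`.
#' @export
build_student <- function(teacher_config,
                          reduction = list(heads = 0.5, layers = 0.5,
                                           width = 0.5, embed = 0.5),
                          seed = 1L) {
  r <- utils::modifyList(list(heads = 1, layers = 1, width = 1, embed = 1),
                         as.list(reduction))
  assert_that(all(unlist(r) > 0 & unlist(r) <= 1),
              "reduction factors must lie in (0, 1]")
  tc <- teacher_config
  n_layers <- max(1L, ceiling(r$layers * length(tc$hidden_sizes)))
  embed <- max(1L, floor(r$embed * tc$embedding_dim))
  heads <- max(1L, floor(r$heads * tc$n_heads))
  sc <- wdnn_config(
    n_snps = tc$n_snps,
    embedding_dim = embed,
    hidden_sizes = pmax(1L, floor(r$width * tc$hidden_sizes[seq_len(n_layers)])),
    activation = tc$activation,
    dropout_rate = tc$dropout_rate,
    use_attention = tc$use_attention,
    n_heads = heads,
    key_dim = max(1L, embed %/% heads),
    cross_pairs = tc$cross_pairs,
    include_raw = tc$include_raw)
  teacher_n <- n_params(wdnn_init(tc, seed = 0L))
  student <- wdnn_init(sc, seed = seed)
  if (student$n_params >= teacher_n) {
    abort(sprintf(
      "student (%d parameters) is not strictly smaller than the teacher (%d)",
      student$n_params, teacher_n))
  }
  student
}

# ---- Adam optimiser over packed parameter vectors ---------------------------

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# binary cross-entropy on the fused logit (labels in {0, 1})
ce_loss_grad <- function(z, y) {
  p <- sigmoid(z)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(loss = mean(-y * log(pc) - (1 - y) * log(1 - pc)),
       dz = (p - y) / length(z))
}

#' Train a Wide-Deep model with minibatch Adam
#'
#' Optimises binary cross-entropy (or a caller-supplied loss) with Adam,
#' minibatch shuffling, and early stopping on validation loss with
#' best-weight restoration. Deterministic given `seed`.
#'
#' @param model An initialised `wdnn_model`.
#' @param X,y Training dosage matrix and 0/1 labels (or a
#'   [cohort_dataset()] as `X`, in which case `y` is taken from it).
#' @param X_val,y_val Optional validation data for early stopping.
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience in epochs (ignored without
#'   validation data).
#' @param seed Integer seed for shuffling and dropout.
#' @param loss_grad_fn Internal hook: function(z, idx) returning
#'   `list(loss, dz, ...)`; defaults to binary cross-entropy against `y`.
#' @param val_loss_fn Internal hook matching `loss_grad_fn` on the
#'   validation logits.
#' @return The trained `wdnn_model`, with a `history` tibble attached
#'   (`epoch`, `train_loss`, `val_loss`, plus any loss components).
#' @export
train_wdnn <- function(model, X, y = NULL, X_val = NULL, y_val = NULL,
                       epochs = 30, batch_size = 64, learning_rate = 0.01,
                       patience = 10, seed = 1L,
                       loss_grad_fn = NULL, val_loss_fn = NULL) {
  if (inherits(X, "cohort_dataset")) { y <- X$labels; X <- X$genotypes }
  if (inherits(X_val, "cohort_dataset")) { y_val <- X_val$labels; X_val <- X_val$genotypes }
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(loss_grad_fn)) {
    loss_grad_fn <- function(z, idx) ce_loss_grad(z, y[idx])
  }
  if (is.null(val_loss_fn) && !is.null(X_val)) {
    val_loss_fn <- function(z) ce_loss_grad(z, y_val)$loss
  }
  withr::local_seed(seed)

  theta <- pack_params(model$params)
  state <- adam_state(length(theta))
  template <- model$params
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  history <- list()
  wait <- 0L

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; ep_parts <- NULL
    for (bi in batches) {
      model$params <- unpack_params(theta, template)
      fw <- wdnn_forward(model, X[bi, , drop = FALSE],
                         training = TRUE, keep_cache = TRUE)
      lg <- loss_grad_fn(fw$logit, bi)
      grads <- wdnn_backward(model, fw$cache, lg$dz)
      st <- adam_step(theta, pack_params(grads), state, learning_rate)
      theta <- st$theta; state <- st$state
      ep_loss <- ep_loss + lg$loss * length(bi)
      parts <- lg[setdiff(names(lg), c("loss", "dz"))]
      if (length(parts) > 0) {
        pv <- unlist(parts) * length(bi)
        ep_parts <- if (is.null(ep_parts)) pv else ep_parts + pv
      }
    }
    model$params <- unpack_params(theta, template)
    row <- list(epoch = epoch, train_loss = ep_loss / n)
    if (!is.null(ep_parts)) row <- c(row, as.list(ep_parts / n))
    if (!is.null(X_val)) {
      vz <- wdnn_forward(model, as.matrix(X_val))$logit
      vloss <- val_loss_fn(vz)
      row$val_loss <- vloss
      if (vloss < best$loss - 1e-9) {
        best <- list(loss = vloss, theta = theta, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    history[[epoch]] <- tibble::as_tibble(row)
    if (!is.null(X_val) && wait >= patience) break
  }

  if (!is.null(X_val) && is.finite(best$loss)) {
    model$params <- unpack_params(best$theta, template)
  }
  model$history <- dplyr::bind_rows(history)
  class(model$history) <- c("training_history", class(model$history))
  model$n_params <- n_params(model)
  model
}

#' Train a teacher model on a cohort
#'
#' Convenience wrapper: stratified validation split, cross-entropy training
#' with early stopping.
#'
#' @param config A `wdnn_config` (e.g. [teacher_config()]).
#' @param dataset Training [cohort_dataset()] (imputed, balanced as desired).
#' @param val_fraction Fraction held out for early stopping.
#' @param epochs,batch_size,learning_rate,patience,seed Passed to
#'   [train_wdnn()].
#' @return A trained `wdnn_model`.
#' @export
train_teacher <- function(config, dataset, val_fraction = 0.15, epochs = 30,
                          batch_size = 64, learning_rate = 0.01, patience = 10,
                          seed = 1L) {
  sp <- stratified_split(dataset, test_fraction = val_fraction,
                         seed = derive_seed(seed, 101))
  model <- wdnn_init(config, seed = seed)
  train_wdnn(model, sp$train, X_val = sp$test,
             epochs = epochs, batch_size = batch_size,
             learning_rate = learning_rate, patience = patience,
             seed = derive_seed(seed, 202))
}
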