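#' Configuration of the multi-head additive attention network
#'
#' Defaults are the reference hyperparameters of the architecture: 3
#' attention heads over the 24-dimensional feature vector, a 16-neuron
#' ReLU fully connected layer, dropout 0.4, Adam with learning rate 0.001,
#' batch size 30, 30 epochs, binary cross-entropy loss.
#'
#' `head_input_mode` selects how heads see the input: `"full_vector"`
#' (default) gives every head the whole 24-vector and a 24-wide weight
#' vector, so 3 heads fuse to 72 dimensions and the attention block holds
#' exactly 3 x (24 x 24 + 24) = 1800 trainable parameters; `"subspace"`
#' restricts each head to its 8-wide feature-family block (fusion width
#' 24).
#'
#' @param n_heads number of attention heads.
#' @param input_dim input feature dimension.
#' @param subspace_layout block widths per head (must sum to `input_dim`).
#' @param hidden_units fully connected layer width.
#' @param dropout dropout rate after the ReLU layer (training only).
#' @param lr,batch_size,epochs Adam learning rate, mini-batch size, epochs.
#' @param head_input_mode `"full_vector"` or `"subspace"`.
#' @param variant `"multi_head"`, `"single_head"` or `"none"` (ablations).
#' @param zscore z-score features with training-set statistics.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed default training seed.
#' @return An `mha_config` list.
#' @export
mha_config <- function(n_heads = 3L, input_dim = 24L,
                       subspace_layout = c(8L, 8L, 8L),
                       hidden_units = 16L, dropout = 0.4, lr = 0.001,
                       batch_size = 30L, epochs = 30L,
                       head_input_mode = c("full_vector", "subspace"),
                       variant = c("multi_head", "single_head", "none"),
                       zscore = TRUE, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, seed = 1L) {
  head_input_mode <- match.arg(head_input_mode)
  variant <- match.arg(variant)
  if (variant == "multi_head" && head_input_mode == "subspace" &&
      sum(subspace_layout) != input_dim)
    stopf("config error: subspace_layout blocks sum to %d, input_dim is %d",
          sum(subspace_layout), input_dim)
  if (variant == "multi_head" && length(subspace_layout) != n_heads)
    stopf("config error: need one subspace block per head")
  structure(list(n_heads = as.integer(n_heads), input_dim = as.integer(input_dim),
                 subspace_layout = as.integer(subspace_layout),
                 hidden_units = as.integer(hidden_units), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 head_input_mode = head_input_mode, variant = variant,
                 zscore = zscore, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "mha_config")
}

# Column index blocks each head attends to, and the fused dimension.
mha_layout <- function(config) {
  switch(config$variant,
    multi_head = {
      if (config$head_input_mode == "full_vector") {
        blocks <- rep(list(seq_len(config$input_dim)), config$n_heads)
      } else {
        ends <- cumsum(config$subspace_layout)
        starts <- c(1L, head(ends, -1) + 1L)
        blocks <- Map(seq.int, starts, ends)
      }
      list(blocks = blocks, fused_dim = sum(lengths(blocks)))
    },
    single_head = list(blocks = list(seq_len(config$input_dim)),
                       fused_dim = config$input_dim),
    none = list(blocks = list(), fused_dim = config$input_dim))
}

glorot <- function(nrow, ncol) {
  l <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -l, l), nrow = nrow)
}

#' Initialise an attention network model
#'
#' Weights are drawn deterministically from the seed (Glorot-uniform
#' matrices, zero biases). The returned model reports its trainable
#' parameter count by component: with the default full-vector multi-head
#' configuration the attention block holds exactly 1800 parameters.
#'
#' @param config an [mha_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An untrained `mha_model`.
#' @export
init_model <- function(config = mha_config(), seed = config$seed) {
  set.seed(derive_seed(seed, 1L))
  lay <- mha_layout(config)
  heads <- lapply(lay$blocks, function(idx) {
    d <- length(idx)
    list(W = glorot(d, d), b = numeric(d))
  })
  W1 <- glorot(config$hidden_units, lay$fused_dim)
  b1 <- numeric(config$hidden_units)
  w2 <- as.numeric(glorot(config$hidden_units, 1))
  b2 <- 0
  n_att <- sum(vapply(heads, function(h) length(h$W) + length(h$b), numeric(1)))
  counts <- c(attention = n_att,
              fusion_head = length(W1) + length(b1),
              output = length(w2) + 1)
  structure(list(config = config, layout = lay, heads = heads,
                 W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 norm = NULL, trained = FALSE, history = NULL,
                 param_counts = counts),
            class = "mha_model")
}

row_softmax <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

apply_norm <- function(model, X) {
  if (is.null(model$norm)) return(X)
  sweep(sweep(X, 2, model$norm$mu), 2, model$norm$sigma, "/")
}

# Batch forward pass. X is n x input_dim (already normalized).
mha_forward_batch <- function(model, X, train = FALSE) {
  cfg <- model$config
  cache <- list(X = X)
  if (cfg$variant == "none") {
    fused <- X
    cache$alphas <- list()
  } else {
    outs <- vector("list", length(model$heads))
    cache$A <- cache$Xh <- vector("list", length(model$heads))
    for (h in seq_along(model$heads)) {
      idx <- model$layout$blocks[[h]]
      Xh <- X[, idx, drop = FALSE]
      S <- Xh %*% t(model$heads[[h]]$W) +
        matrix(model$heads[[h]]$b, nrow(X), length(idx), byrow = TRUE)
      A <- row_softmax(S)
      outs[[h]] <- A * Xh
      cache$A[[h]] <- A; cache$Xh[[h]] <- Xh
    }
    fused <- do.call(cbind, outs)
    cache$alphas <- cache$A
  }
  H <- fused %*% t(model$W1) +
    matrix(model$b1, nrow(X), length(model$b1), byrow = TRUE)
  R <- pmax(H, 0)
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    mask <- matrix(stats::rbinom(length(R), 1, keep) / keep, nrow(R))
    D <- R * mask
    cache$mask <- mask
  } else D <- R
  z <- as.numeric(D %*% model$w2 + model$b2)
  p <- 1 / (1 + exp(-z))
  cache$fused <- fused; cache$H <- H; cache$D <- D
  list(prob = p, cache = cache)
}

# Gradients of mean BCE loss w.r.t. every parameter.
mha_backward <- function(model, fwd, y) {
  cfg <- model$config
  cache <- fwd$cache
  n <- length(y)
  dz <- (fwd$prob - y) / n
  grads <- list(b2 = sum(dz), w2 = as.numeric(t(cache$D) %*% dz))
  dD <- outer(dz, model$w2)
  dR <- if (!is.null(cache$mask)) dD * cache$mask else dD
  dH <- dR * (cache$H > 0)
  grads$W1 <- t(dH) %*% cache$fused
  grads$b1 <- colSums(dH)
  dfused <- dH %*% model$W1
  if (cfg$variant != "none") {
    grads$heads <- vector("list", length(model$heads))
    off <- 0L
    for (h in seq_along(model$heads)) {
      idx <- model$layout$blocks[[h]]
      d <- length(idx)
      dO <- dfused[, (off + 1):(off + d), drop = FALSE]
      off <- off + d
      A <- cache$A[[h]]; Xh <- cache$Xh[[h]]
      dA <- dO * Xh
      dS <- A * (dA - rowSums(A * dA))
      grads$heads[[h]] <- list(W = t(dS) %*% Xh, b = colSums(dS))
    }
  }
  grads
}

#' Additive attention forward pass for one feature vector
#'
#' Computes, per head, the softmax attention weights
#' `alpha_h = softmax(W_h x + b_h)` and the element-wise weighted output
#' `alpha_h * x`; head outputs are concatenated in stable head order into
#' the fused vector (72-dimensional under the default full-vector
#' three-head configuration). Each `alpha_h` is non-negative and sums to 1.
#'
#' @param model an `mha_model` (any variant with attention heads).
#' @param x numeric input vector of length `input_dim` (already on the
#'   model's normalized scale; no z-scoring is applied here).
#' @return List with `x_fused` and `alpha` (list of per-head weight
#'   vectors).
#' @export
attention_forward <- function(model, x) {
  if (any(!is.finite(x))) stopf("input error: non-finite input")
  if (length(x) != model$config$input_dim)
    stopf("shape error: expected length-%d input", model$config$input_dim)
  fwd <- mha_forward_batch(model, matrix(x, nrow = 1), train = FALSE)
  list(x_fused = as.numeric(fwd$cache$fused),
       alpha = lapply(fwd$cache$alphas, as.numeric))
}

#' Full network forward pass (inference)
#'
#' Attention fusion, 16-neuron ReLU layer, sigmoid output. Dropout is
#' disabled, so repeated calls are identical. If the model was trained
#' with z-scoring, the stored training statistics are applied first.
#'
#' @param model an `mha_model`.
#' @param x length-`input_dim` vector or n x `input_dim` matrix.
#' @return Probability (or vector of probabilities) in `(0, 1)` that the
#'   input is a depression epoch.
#' @export
mha_predict <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$config$input_dim)
    stopf("shape error: expected %d columns", model$config$input_dim)
  if (any(!is.finite(x))) stopf("input error: non-finite input")
  X <- apply_norm(model, x)
  as.numeric(mha_forward_batch(model, X, train = FALSE)$prob)
}

#' @export
predict_scores.mha_model <- function(model, features) mha_predict(model, features)

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_make <- function(template) lapply(template, function(x) x * 0)

#' Train the attention network
#'
#' Mini-batch Adam on binary cross-entropy for a fixed number of epochs
#' (no early stopping). Features are z-scored with training-set statistics
#' stored on the model for inference. Shuffling and dropout are driven by
#' the seed, so training is bit-reproducible on a single thread.
#'
#' @param model an initialised `mha_model`.
#' @param X N x `input_dim` training features.
#' @param y binary labels (depression = 1); both classes required.
#' @param seed training seed (defaults to the config seed).
#' @param X_val,y_val optional validation split recorded in the history.
#' @return The trained model; `model$history` holds per-epoch train (and
#'   validation) loss/accuracy plus a `converged_epoch` attribute (first
#'   epoch reaching 99% of the final training accuracy).
#' @export
mha_train <- function(model, X, y, seed = model$config$seed,
                      X_val = NULL, y_val = NULL) {
  cfg <- model$config
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stopf("training refused: single-class labels")
  if (cfg$zscore) {
    mu <- colMeans(X)
    sigma <- apply(X, 2, sd)
    sigma[sigma == 0] <- 1
    model$norm <- list(mu = mu, sigma = sigma)
  }
  Xn <- apply_norm(model, X)
  Xv <- if (!is.null(X_val)) apply_norm(model, X_val)
  n <- nrow(Xn)
  flat <- mha_flatten(model)
  mstate <- adam_make(flat); vstate <- adam_make(flat); tstep <- 0L
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
  set.seed(derive_seed(seed, 2L))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      fwd <- mha_forward_batch(model, Xn[idx, , drop = FALSE], train = TRUE)
      grads <- mha_backward(model, fwd, y[idx])
      gflat <- mha_flatten_grads(model, grads)
      tstep <- tstep + 1L
      for (k in names(flat)) {
        mstate[[k]] <- cfg$beta1 * mstate[[k]] + (1 - cfg$beta1) * gflat[[k]]
        vstate[[k]] <- cfg$beta2 * vstate[[k]] + (1 - cfg$beta2) * gflat[[k]]^2
        mhat <- mstate[[k]] / (1 - cfg$beta1^tstep)
        vhat <- vstate[[k]] / (1 - cfg$beta2^tstep)
        flat[[k]] <- flat[[k]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
      }
      model <- mha_unflatten(model, flat)
    }
    p_tr <- as.numeric(mha_forward_batch(model, Xn, train = FALSE)$prob)
    hist$train_loss[ep] <- bce_loss(p_tr, y)
    hist$train_acc[ep] <- mean((p_tr >= 0.5) == (y == 1))
    if (!is.null(Xv)) {
      p_v <- as.numeric(mha_forward_batch(model, Xv, train = FALSE)$prob)
      hist$val_loss[ep] <- bce_loss(p_v, as.numeric(y_val))
      hist$val_acc[ep] <- mean((p_v >= 0.5) == (y_val == 1))
    }
  }
  final <- hist$train_acc[cfg$epochs]
  attr(hist, "converged_epoch") <- min(which(hist$train_acc >= 0.99 * final))
  model$history <- hist
  model$trained <- TRUE
  model
}

# Flatten parameters to a named list of arrays for Adam / serialization.
mha_flatten <- function(model) {
  flat <- list(W1 = model$W1, b1 = model$b1, w2 = model$w2, b2 = model$b2)
  for (h in seq_along(model$heads)) {
    flat[[paste0("Wh", h)]] <- model$heads[[h]]$W
    flat[[paste0("bh", h)]] <- model$heads[[h]]$b
  }
  flat
}

mha_flatten_grads <- function(model, grads) {
  flat <- list(W1 = grads$W1, b1 = grads$b1, w2 = grads$w2, b2 = grads$b2)
  for (h in seq_along(model$heads)) {
    flat[[paste0("Wh", h)]] <- grads$heads[[h]]$W
    flat[[paste0("bh", h)]] <- grads$heads[[h]]$b
  }
  flat
}

mha_unflatten <- function(model, flat) {
  model$W1 <- flat$W1; model$b1 <- flat$b1
  model$w2 <- flat$w2; model$b2 <- flat$b2
  for (h in seq_along(model$heads)) {
    model$heads[[h]]$W <- flat[[paste0("Wh", h)]]
    model$heads[[h]]$b <- flat[[paste0("bh", h)]]
  }
  model
}

#' Central-finite-difference gradient check
#'
#' Compares the analytic gradients of the mean binary cross-entropy loss
#' with central finite differences over every trainable parameter
#' (dropout disabled). Returns the maximum relative error, which should be
#' well below 1e-4 for a correct implementation.
#'
#' @param model an `mha_model`.
#' @param X small batch of inputs (already on the model scale).
#' @param y batch labels.
#' @param eps_fd finite-difference step.
#' @return Maximum relative gradient error across parameters.
#' @export
mha_gradient_check <- function(model, X, y, eps_fd = 1e-5) {
  fwd <- mha_forward_batch(model, X, train = FALSE)
  grads <- mha_flatten_grads(model, mha_backward(model, fwd, y))
  flat <- mha_flatten(model)
  loss_at <- function(fl) {
    m <- mha_unflatten(model, fl)
    bce_loss(mha_forward_batch(m, X, train = FALSE)$prob, y)
  }
  worst <- 0
  for (k in names(flat)) {
    par <- flat[[k]]
    for (i in seq_along(par)) {
      fl <- flat
      fl[[k]][i] <- par[i] + eps_fd
      up <- loss_at(fl)
      fl[[k]][i] <- par[i] - eps_fd
      dn <- loss_at(fl)
      num <- (up - dn) / (2 * eps_fd)
      ana <- grads[[k]][i]
      rel <- abs(num - ana) / max(1e-8, abs(num) + abs(ana))
      worst <- max(worst, rel)
    }
  }
  worst
}

#' Construct an ablation variant of the network
#'
#' `"none"` removes attention entirely (features go straight to the dense
#' layer), `"single_head"` uses one attention head over the full feature
#' vector (fused width = input width), `"multi_head"` is the full model.
#' All variants share identical dense-layer and training hyperparameters.
#'
#' @param kind `"none"`, `"single_head"` or `"multi_head"`.
#' @param config base [mha_config()].
#' @param seed initialisation seed.
#' @return An initialised `mha_model` of the requested variant.
#' @export
ablation_variant <- function(kind = c("multi_head", "single_head", "none"),
                             config = mha_config(), seed = config$seed) {
  kind <- match.arg(kind)
  config$variant <- kind
  init_model(config, seed = seed)
}

#' Stratified k-fold split
#'
#' Seeded stratified assignment: within each class, indices are shuffled
#' and dealt round-robin to folds, so every fold keeps the class ratio.
#' The same split object is shared across models so comparisons are paired
#' (a requirement of the DeLong test).
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of `k` integer vectors of test indices (disjoint, covering).
#' @export
make_stratified_folds <- function(y, k = 5L, seed = 1L) {
  if (length(y) < k) stopf("parameter error: fewer samples than folds")
  set.seed(derive_seed(seed, 3L))
  folds <- vector("list", k)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    grp <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}

#' Stratified k-fold cross-validation of the attention network
#'
#' Per fold: z-scoring statistics are fitted on the training split only,
#' the model is trained for the configured epochs, and metrics are
#' computed exclusively on the held-out fold. Fold test sets are disjoint
#' and cover the data.
#'
#' @param X N x `input_dim` features.
#' @param y binary labels.
#' @param config an [mha_config()].
#' @param k number of folds.
#' @param seed seed for the fold split and training.
#' @param folds optional precomputed split from [make_stratified_folds()].
#' @return List with `fold_reports` (per-fold [compute_metrics()] output
#'   plus AUC), `mean`/`sd` metric summaries, `oof_scores` (out-of-fold
#'   scores aligned with rows of `X`), `folds`, and `models`.
#' @export
cross_validate <- function(X, y, config = mha_config(), k = 5L, seed = 1L,
                           folds = NULL) {
  y <- as.integer(y)
  folds <- folds %||% make_stratified_folds(y, k, seed)
  oof <- rep(NA_real_, length(y))
  reports <- vector("list", length(folds))
  models <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(y), test)
    stopifnot(length(intersect(train, test)) == 0)
    model <- init_model(config, seed = derive_seed(seed, 10L + f))
    model <- mha_train(model, X[train, , drop = FALSE], y[train],
                       seed = derive_seed(seed, 20L + f))
    sc <- mha_predict(model, X[test, , drop = FALSE])
    oof[test] <- sc
    reports[[f]] <- fold_report(sc, y[test], fold_id = f, model_tag = config$variant)
    models[[f]] <- model
  }
  summarize_cv(reports, oof, y, folds, models)
}
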