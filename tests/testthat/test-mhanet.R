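test_that("model initialisation reports the architecture parameter counts", {
  m <- init_model(mha_config(), seed = 1)
  expect_equal(unname(m$param_counts["attention"]), 3 * (24 * 24 + 24)) # 1800
  expect_equal(unname(m$param_counts["fusion_head"]), 16 * 72 + 16)
  expect_equal(unname(m$param_counts["output"]), 17)
  m2 <- init_model(mha_config(), seed = 1)
  expect_identical(m$heads, m2$heads)
  expect_identical(m$W1, m2$W1)
  expect_error(mha_config(head_input_mode = "subspace",
                          subspace_layout = c(8, 8, 7)), "config error")
  sub <- init_model(mha_config(head_input_mode = "subspace"), seed = 1)
  expect_equal(unname(sub$param_counts["attention"]), 3 * (8 * 8 + 8))
  expect_equal(sub$layout$fused_dim, 24L)
})

test_that("attention forward obeys the softmax-weighting contract", {
  m <- init_model(mha_config(), seed = 2)
  x <- rnorm(24)
  af <- attention_forward(m, x)
  expect_length(af$x_fused, 72L)
  for (a in af$alpha) {
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-6)
  }
  # zero weights -> uniform attention; zero input -> zero fusion
  m0 <- m
  for (h in seq_along(m0$heads)) {
    m0$heads[[h]]$W <- m0$heads[[h]]$W * 0
    m0$heads[[h]]$b <- m0$heads[[h]]$b * 0
  }
  af0 <- attention_forward(m0, x)
  for (a in af0$alpha) expect_equal(a, rep(1 / 24, 24), tolerance = 1e-12)
  expect_equal(attention_forward(m, rep(0, 24))$x_fused, rep(0, 72))
  expect_error(attention_forward(m, c(NA, rnorm(23))), "non-finite")
})

test_that("inference is deterministic, bounded and shape-checked", {
  m <- init_model(mha_config(), seed = 3)
  x <- rnorm(24)
  p1 <- mha_predict(m, x); p2 <- mha_predict(m, x)
  expect_identical(p1, p2) # dropout off at inference
  expect_true(p1 > 0 && p1 < 1)
  mz <- m
  mz$W1 <- mz$W1 * 0; mz$b1 <- mz$b1 * 0
  mz$w2 <- mz$w2 * 0; mz$b2 <- 0
  expect_equal(mha_predict(mz, x), 0.5) # sigmoid(0)
  expect_error(mha_predict(m, rnorm(23)), "shape")
})

test_that("analytic gradients match finite differences in every variant", {
  set.seed(81)
  X <- matrix(rnorm(5 * 24), 5)
  y <- c(1, 0, 1, 1, 0)
  for (cfg in list(mha_config(),
                   mha_config(head_input_mode = "subspace"),
                   mha_config(variant = "single_head"),
                   mha_config(variant = "none"))) {
    m <- init_model(cfg, seed = 4)
    expect_lt(mha_gradient_check(m, X, y), 1e-4)
  }
})

test_that("training learns separable data deterministically", {
  set.seed(82)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 24), n) + outer(y, c(rep(1.2, 8), rep(0, 16)))
  m <- init_model(mha_config(), seed = 5)
  m <- mha_train(m, X, y, seed = 6)
  expect_true(m$trained)
  expect_gt(m$history$train_acc[30], m$history$train_acc[1])
  expect_gt(m$history$train_acc[30], 0.85)
  expect_false(is.null(m$norm)) # z-scoring stats stored for inference
  m2 <- mha_train(init_model(mha_config(), seed = 5), X, y, seed = 6)
  expect_identical(mha_flatten(m), mha_flatten(m2)) # bit-stable training
  expect_error(mha_train(init_model(), X, rep(1, n)), "single-class")
})

test_that("training on permuted labels stays at chance", {
  fm <- features_small()
  set.seed(83)
  accs <- vapply(1:5, function(s) {
    perm <- sample(fm$labels)
    idx <- sample(length(perm))
    tr <- idx[1:140]; te <- idx[141:200]
    m <- mha_train(init_model(mha_config(), seed = s),
                   fm$features[tr, ], perm[tr], seed = s)
    mean((mha_predict(m, fm$features[te, ]) >= 0.5) == (perm[te] == 1))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("cross-validation folds are stratified, disjoint and covering", {
  y <- rep(c(0, 1), each = 51)
  folds <- make_stratified_folds(y, 5, seed = 7)
  expect_length(folds, 5L)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(y)) # partition
  for (f in folds) expect_lte(abs(sum(y[f] == 1) - sum(y[f] == 0)), 1)
  expect_error(make_stratified_folds(c(0, 1), 5), "fewer samples")

  fm <- features_small()
  cv <- cross_validate(fm$features, fm$labels, mha_config(), k = 5, seed = 8)
  expect_length(cv$fold_reports, 5L)
  expect_true(all(is.finite(cv$oof_scores)))
  expect_equal(sum(vapply(cv$fold_reports, function(r) r$n_test, numeric(1))),
               200)
  # per-fold z-scoring uses training statistics only
  test1 <- cv$folds[[1]]
  train1 <- setdiff(seq_along(fm$labels), test1)
  expect_equal(cv$models[[1]]$norm$mu, colMeans(fm$features[train1, ]))
})

test_that("ablation variants have the documented shapes", {
  none <- ablation_variant("none", mha_config(), seed = 9)
  expect_length(none$heads, 0L)
  expect_equal(unname(none$param_counts["attention"]), 0)
  expect_equal(none$layout$fused_dim, 24L)
  single <- ablation_variant("single_head", mha_config(), seed = 9)
  expect_length(single$heads, 1L)
  expect_equal(single$layout$fused_dim, 24L)
  multi <- ablation_variant("multi_head", mha_config(), seed = 9)
  expect_equal(multi$layout$fused_dim, 72L)
})

test_that("model serialization round-trips predictions exactly", {
  fm <- features_small()
  idx <- c(1:30, 101:130) # cohort rows are class-blocked; take both classes
  m <- mha_train(init_model(mha_config(), seed = 10),
                 fm$features[idx, ], fm$labels[idx], seed = 10)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(mha_predict(m2, fm$features), mha_predict(m, fm$features),
               tolerance = 1e-12)
})
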