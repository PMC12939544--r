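#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. The U statistic counts
#' pairs with `x > y` plus half the ties. The p-value is exact (full
#' enumeration) when the combined sample size is at most 12 and there are
#' no ties, otherwise a normal approximation with tie and continuity
#' correction is used; both paths are delegated to [stats::wilcox.test()].
#'
#' @param x,y numeric samples (non-empty).
#' @return List with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stopf("parameter error: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Welch independent-samples t-test (two-sided)
#'
#' Unequal-variance form with Welch-Satterthwaite degrees of freedom.
#' If both samples are constant with equal means the statistic is defined
#' as 0 with p = 1 (no evidence of a difference).
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test_ind <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stopf("parameter error: need at least 2 observations per sample")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p_value = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Screen every feature column for class separation
#'
#' Runs the chosen two-sample test per (family, channel) feature column at
#' alpha = 0.05. No multiple-testing correction is applied by default,
#' matching the raw per-channel screening convention; a Benjamini-Hochberg
#' adjusted column is available via `adjust = "BH"`. Screening is
#' diagnostic: non-significant channels are reported, not removed.
#'
#' @param features N x 24 feature matrix (named columns).
#' @param labels binary labels (depression = 1).
#' @param test `"mwu"` (Mann-Whitney U) or `"ttest"` (Welch t).
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with `feature`, `family`, `channel`, `statistic`,
#'   `p_value`, `significant` (and `p_adj` if adjusted); attribute
#'   `n_significant` holds the per-family significant counts.
#' @export
screen_features <- function(features, labels, test = c("mwu", "ttest"),
                            alpha = 0.05, adjust = c("none", "BH")) {
  test <- match.arg(test); adjust <- match.arg(adjust)
  if (length(unique(labels)) < 2)
    stopf("cohort error: both classes must be present")
  cn <- colnames(features)
  res <- lapply(seq_along(cn), function(j) {
    v <- features[, j]
    x <- v[labels == 1]; y <- v[labels == 0]
    if (sd(v) == 0) {
      warning(sprintf("constant feature column %s; p set to 1", cn[j]))
      stat <- NA_real_; p <- 1
    } else if (test == "mwu") {
      r <- mann_whitney_u(x, y); stat <- r$U; p <- r$p_value
    } else {
      r <- t_test_ind(x, y); stat <- r$t; p <- r$p_value
    }
    parts <- strsplit(cn[j], "_", fixed = TRUE)[[1]]
    data.frame(feature = cn[j], family = parts[1],
               channel = paste(parts[-1], collapse = "_"),
               statistic = stat, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adj < alpha
  }
  attr(out, "n_significant") <- tapply(out$significant, out$family, sum)
  out
}

# DeLong structural components: psi(X_i, Y_j) averaged over the other
# argument, for positive-class scores X and negative-class scores Y.
delong_components <- function(scores, labels) {
  X <- scores[labels == 1]; Y <- scores[labels == 0]
  m <- length(X); n <- length(Y)
  psi <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors evaluated on the same labelled
#' instances, using the structural-component covariance estimate. The AUC
#' is the mid-rank (Mann-Whitney) estimator, identical to
#' `U / (n_pos * n_neg)`.
#'
#' @param scores_a,scores_b paired score vectors (higher = more positive).
#' @param labels binary labels (positive = 1); both classes required.
#' @return List with `auc1`, `auc2`, `z`, `p_value`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stopf("parameter error: both classes must be present")
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stopf("scores must be paired on the same labelled instances")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / ca$m + s01 / ca$n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = ca$auc, auc2 = cb$auc, z = z, p_value = p, var_diff = var_diff)
}

#' Permutation feature importance
#'
#' Accuracy drop when one feature column is permuted (averaged over
#' `n_perm` seeded permutations), min-max normalized so the most important
#' feature scores exactly 1. Applies uniformly to any model for which
#' [predict_scores()] is defined, so the same ranking procedure serves the
#' attention network and the baselines.
#'
#' @param model a trained model with a [predict_scores()] method.
#' @param features held-out N x p feature matrix.
#' @param labels held-out binary labels.
#' @param seed integer seed.
#' @param n_perm permutations per column, default 20.
#' @return Data frame with `feature`, `mean_drop`, `importance`, sorted by
#'   importance (descending).
#' @export
feature_importance <- function(model, features, labels, seed = 1L,
                               n_perm = 20L) {
  base_acc <- mean((predict_scores(model, features) >= 0.5) == (labels == 1))
  p <- ncol(features)
  drops <- numeric(p)
  for (j in seq_len(p)) {
    set.seed(derive_seed(seed, j))
    accs <- vapply(seq_len(n_perm), function(k) {
      Xp <- features
      Xp[, j] <- Xp[sample(nrow(Xp)), j]
      mean((predict_scores(model, Xp) >= 0.5) == (labels == 1))
    }, numeric(1))
    drops[j] <- base_acc - mean(accs)
  }
  rng <- range(drops)
  imp <- if (diff(rng) == 0) rep(1, p) else (drops - rng[1]) / diff(rng)
  out <- data.frame(feature = colnames(features), mean_drop = drops,
                    importance = imp, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Predicted positive-class scores of a trained model
#'
#' Generic used by the importance ranking and the report layer; methods
#' exist for the attention network, the ablation variants, the recurrent
#' baseline, and plain functions.
#'
#' @param model trained model object.
#' @param features N x p feature matrix.
#' @return Numeric vector of scores in `[0, 1]` (or decision values for
#'   margin-based models).
#' @export
predict_scores <- function(model, features) UseMethod("predict_scores")

#' @export
predict_scores.function <- function(model, features) model(features)
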