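#' Classification metrics from confusion counts
#'
#' The positive class is depression (label 1). Headline precision, recall
#' and F1 are the depression-class values; per-class and macro values are
#' always included so either convention can be read off. Zero-denominator
#' precision/recall are defined as 0 and flagged.
#'
#' @param tn,fp,fn,tp non-negative confusion counts.
#' @return List with `confusion`, `accuracy`, `precision`, `recall`, `f1`
#'   (headline = depression class), `per_class` (rows `depression`,
#'   `negative_emotion`), `macro_f1`, `fp_fn_gap` (the |fp - fn| class-bias
#'   diagnostic), `undefined` flags.
#' @export
compute_metrics <- function(tn, fp, fn, tp) {
  counts <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(counts < 0)) stopf("parameter error: negative confusion count")
  total <- sum(counts)
  if (total == 0) stopf("parameter error: empty confusion matrix")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  prec_pos <- safe_div(tp, tp + fp)
  rec_pos <- safe_div(tp, tp + fn)
  prec_neg <- safe_div(tn, tn + fn)
  rec_neg <- safe_div(tn, tn + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  per_class <- data.frame(
    class = c("depression", "negative_emotion"),
    precision = c(prec_pos, prec_neg),
    recall = c(rec_pos, rec_neg),
    f1 = c(f1(prec_pos, rec_pos), f1(prec_neg, rec_neg)),
    stringsAsFactors = FALSE)
  list(confusion = counts,
       total = total,
       accuracy = (tp + tn) / total,
       precision = prec_pos, recall = rec_pos,
       f1 = per_class$f1[1],
       per_class = per_class,
       macro_f1 = mean(per_class$f1),
       fp_fn_gap = abs(fp - fn),
       undefined = c(precision = (tp + fp) == 0, recall = (tp + fn) == 0))
}

#' ROC curve and AUC by threshold sweep
#'
#' Thresholds sweep the unique score values (equal scores collapse to one
#' threshold step, consistent with the mid-rank AUC); the curve runs
#' monotonically from (0, 0) to (1, 1) and the AUC is the trapezoidal
#' area, equal to the rank-based (Mann-Whitney) estimator to numerical
#' precision.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (positive = 1).
#' @return List with `roc` (data frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stopf("parameter error: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE) # last index of each tied score block
  tpr <- c(0, cumsum(y == 1)[keep] / n_pos)
  fpr <- c(0, cumsum(y == 0)[keep] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, s[keep])),
       auc = auc)
}

# Per-fold evaluation report from held-out scores. `pred` overrides the
# thresholding for models whose scores are margins rather than
# probabilities (e.g. SVM decision values).
fold_report <- function(scores, labels, threshold = 0.5, fold_id = NA,
                        model_tag = "", feature_subset = "all", pred = NULL) {
  if (is.null(pred)) pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  m <- compute_metrics(tn, fp, fn, tp)
  ra <- roc_auc(scores, labels)
  m$auc <- ra$auc
  m$roc <- ra$roc
  m$scores <- scores
  m$fold_id <- fold_id
  m$model_tag <- model_tag
  m$feature_subset <- feature_subset
  m$n_test <- length(labels)
  m
}

# Aggregate fold reports into the cross-validation summary object.
summarize_cv <- function(reports, oof, y, folds, models = NULL) {
  metric_names <- c("accuracy", "precision", "recall", "f1", "auc")
  tab <- sapply(metric_names, function(mn)
    vapply(reports, function(r) r[[mn]], numeric(1)))
  pooled <- roc_auc(oof, y)
  structure(list(fold_reports = reports,
                 mean = colMeans(tab), sd = apply(tab, 2, sd),
                 oof_scores = oof, labels = y, folds = folds,
                 pooled_auc = pooled$auc, models = models),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s)\n", length(x$fold_reports),
              x$fold_reports[[1]]$model_tag))
  for (mn in names(x$mean))
    cat(sprintf("  %-10s %.4f +/- %.4f\n", mn, x$mean[[mn]], x$sd[[mn]]))
  cat(sprintf("  pooled out-of-fold AUC: %.4f\n", x$pooled_auc))
  invisible(x)
}

#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates the three stages end to end on generated data: simulate a
#' balanced cohort, extract the 24-dimensional feature matrix, screen the
#' features, cross-validate the attention network with its ablations and
#' baselines, and write all artifacts (manifest, feature CSV + parameter
#' sidecar, screening table, metrics JSON, importance ranking, ROC points;
#' optionally PNG figures) to the output directory. Fully reproducible
#' from `(config, seed)`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_class samples per class, default 510.
#' @param seed master seed.
#' @param config an [mha_config()].
#' @param k folds for cross-validation.
#' @param run_ablations,run_baselines include those stages.
#' @param make_plots write ROC/importance PNG figures.
#' @param progress print progress marks during feature extraction.
#' @return Invisibly, a list with the feature matrix, screening table,
#'   cross-validation results and file manifest.
#' @export
run_pipeline <- function(out_dir, n_per_class = 510L, seed = 1L,
                         config = mha_config(), k = 5L,
                         run_ablations = TRUE, run_baselines = TRUE,
                         make_plots = FALSE, progress = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    cohort <- generate_cohort(n_per_class, seed = seed)
    stage <- "extract"
    fm <- build_feature_matrix(cohort, progress = progress)
    write_feature_matrix(fm, file.path(out_dir, "features.csv"))
    stage <- "screen"
    scr_mwu <- screen_features(fm$features, fm$labels, test = "mwu")
    scr_t <- screen_features(fm$features, fm$labels, test = "ttest")
    scr_mwu$test <- "mwu"; scr_t$test <- "ttest"
    screening <- rbind(scr_mwu, scr_t)
    write.csv(screening, file.path(out_dir, "screening.csv"), row.names = FALSE)
    stage <- "train"
    folds <- make_stratified_folds(fm$labels, k, seed)
    cv_main <- cross_validate(fm$features, fm$labels, config, k = k,
                              seed = seed, folds = folds)
    results <- list(multi_head = cv_main)
    if (run_ablations) {
      stage <- "ablate"
      for (kind in c("single_head", "none")) {
        cfg <- config; cfg$variant <- kind
        results[[kind]] <- cross_validate(fm$features, fm$labels, cfg,
                                          k = k, seed = seed, folds = folds)
      }
    }
    if (run_baselines) {
      stage <- "baselines"
      results$svm <- svm_nested_cv(fm$features, fm$labels, seed = seed,
                                   folds = folds)
      results$xgboost <- xgb_cv(fm$features, fm$labels, seed = seed,
                                folds = folds)
      results$rnn <- rnn_cv(fm$features, fm$labels, seed = seed,
                            folds = folds)
    }
    stage <- "report"
    metrics <- lapply(results, function(r)
      list(mean = as.list(r$mean), sd = as.list(r$sd),
           pooled_auc = r$pooled_auc,
           n_test_per_fold = vapply(r$fold_reports, function(fr) fr$n_test,
                                    numeric(1))))
    dl <- if (run_baselines)
      delong_test(results$multi_head$oof_scores, results$svm$oof_scores,
                  fm$labels)
    metrics$delong_multi_vs_svm <- dl
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    imp_model <- cv_main$models[[1]]
    hold <- folds[[1]]
    imp <- feature_importance(imp_model, fm$features[hold, , drop = FALSE],
                              fm$labels[hold], seed = seed)
    write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
    write.csv(cv_main$fold_reports[[1]]$roc, file.path(out_dir, "roc_fold1.csv"),
              row.names = FALSE)
    manifest <- data.frame(
      artifact = c("features.csv", "features_params.json", "screening.csv",
                   "metrics.json", "importance.csv", "roc_fold1.csv"),
      stringsAsFactors = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    if (make_plots) {
      grDevices::png(file.path(out_dir, "roc.png"), width = 600, height = 600)
      plot(cv_main$fold_reports[[1]]$roc$fpr, cv_main$fold_reports[[1]]$roc$tpr,
           type = "l", xlab = "False positive rate", ylab = "True positive rate",
           main = "Fold-1 ROC (multi-head attention)")
      graphics::abline(0, 1, lty = 2)
      grDevices::dev.off()
    }
    list(features = fm, screening = screening, results = results,
         importance = imp, manifest = manifest)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}
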