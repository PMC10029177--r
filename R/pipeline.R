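## End-to-end orchestration: annotate -> impute -> split -> (tune) ->
## train -> evaluate -> explain, for one CNV type and task, writing
## machine-readable artifacts. This backs both R usage and the
## command-line entry point (exec/cnvpatho).

#' Run the full training/evaluation pipeline on a labelled CNV set
#'
#' Restricts to the requested CNV type, annotates against the bundle,
#' splits stratified 7:3 (configurable), fits imputation medians on the
#' training partition only, optionally tunes hyperparameters by
#' cross-validated random search, trains the gradient-boosted model,
#' evaluates on the held-out partition and computes SHAP attributions.
#'
#' @param cnvs labelled \code{cnv_records}.
#' @param bundle \code{cnv_bundle}.
#' @param task a \code{cnv_task} (binary tasks use only benign/pathogenic
#'   rows, mirroring training on those two classes alone).
#' @param seed integer seed driving the split, tuning and training.
#' @param registry feature registry (default 79 features).
#' @param ratio training fraction.
#' @param tune_trials random-search trials (0 = use \code{hp} as given).
#' @param cv_folds folds for tuning.
#' @param hp hyperparameters when not tuning.
#' @param outdir if non-NULL, artifacts (feature matrix, predictions,
#'   report JSON, SHAP ranking) are written there.
#' @return list: model, report, shap, split, matrix, paths.
#' @export
run_pipeline <- function(cnvs, bundle, task, seed,
                         registry = default_feature_registry(),
                         ratio = 0.7, tune_trials = 0, cv_folds = 3,
                         hp = list(eta = 0.1, gamma = 0, max_depth = 6,
                                   min_child_weight = 1, subsample = 0.9,
                                   nrounds = 150),
                         outdir = NULL) {
  stopifnot(inherits(task, "cnv_task"))
  keep <- cnvs$cnv_type == task$cnv_type & cnvs$label %in% task$classes
  sub <- cnvs[keep, , drop = FALSE]
  if (nrow(sub) == 0) stop("run_pipeline: no CNVs for this task")
  fm <- annotate_cnvs(sub, bundle, registry)
  labels <- sub$label
  split <- split_dataset(labels, ratio = ratio, seed = seed)
  fm_train <- new_feature_matrix(registry,
                                 fm$values[split$train, , drop = FALSE])
  fm_test <- new_feature_matrix(registry,
                                fm$values[split$test, , drop = FALSE])
  medians <- suppressWarnings(fit_impute(fm_train))
  fm_train <- apply_impute(fm_train, medians)
  fm_test <- apply_impute(fm_test, medians)
  if (tune_trials > 0)
    hp <- tune_hyperparameters(fm_train, labels[split$train], task,
                               n_trials = tune_trials, cv_folds = cv_folds,
                               seed = seed)
  model <- train_model(fm_train, labels[split$train], hp, task, seed = seed)
  report <- evaluate_model(model, fm_test, labels[split$test])
  shap <- shap_attributions(model, fm_test)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      matrix = file.path(outdir, "feature_matrix.tsv"),
      predictions = file.path(outdir, "predictions.tsv"),
      report = file.path(outdir, "report.json"),
      shap = file.path(outdir, "shap_ranking.tsv"))
    write_feature_matrix(apply_impute(fm, medians), paths$matrix)
    preds <- predict(model, fm_test)
    preds$truth <- labels[split$test]
    utils::write.table(preds, paths$predictions, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(report_to_list(report, seed), paths$report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rk <- rank_features_by_shap(shap, top_k = length(shap$features))
    utils::write.table(
      data.frame(feature = rk,
                 sum_abs_shap = abs_attr_by_feature(shap)[
                   match(rk, shap$features)]),
      paths$shap, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(model = model, report = report, shap = shap, split = split,
       matrix = fm, medians = medians, hp = hp, paths = paths)
}

report_to_list <- function(report, seed = NULL) {
  list(task = report$task$task, cnv_type = report$task$cnv_type,
       seed = seed, n = report$n, accuracy = report$accuracy,
       auc = as.list(report$auc),
       per_class = lapply(report$per_class, function(m)
         m[c("sensitivity", "specificity", "balanced_accuracy",
             "precision", "f1")]),
       undefined_classes = report$undefined_classes)
}
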