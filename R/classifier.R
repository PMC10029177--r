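## Gradient-boosted-tree pathogenicity classifiers (XGBoost), five-tier and
## binary, trained separately for loss and gain CNVs. Hyperparameters
## {eta, gamma, max_depth, min_child_weight, subsample, nrounds} are tuned
## by seeded random search under stratified k-fold cross-validation,
## maximizing mean one-vs-rest AUC; all other XGBoost parameters stay at
## their defaults. Training is single-threaded and seeded for exact
## reproducibility.

#' Define a classification task
#' @param task "five_tier" (ACMG scale) or "binary" (benign vs pathogenic).
#' @param cnv_type "loss" or "gain" (models are type-specific).
#' @return list of class \code{cnv_task}.
#' @export
task_spec <- function(task = c("five_tier", "binary"),
                      cnv_type = c("loss", "gain")) {
  task <- match.arg(task); cnv_type <- match.arg(cnv_type)
  classes <- if (task == "five_tier") PATHOGENICITY_LEVELS
             else c("benign", "pathogenic")
  out <- list(task = task, cnv_type = cnv_type, classes = classes,
              positive_class = if (task == "binary") "pathogenic" else NA)
  class(out) <- "cnv_task"
  out
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(code)
}

#' Stratified train/test split
#'
#' Disjoint partitions whose union is the input, stratified so per-class
#' proportions match the ratio within rounding; reproducible for a fixed
#' seed.
#'
#' @param labels class label per row.
#' @param ratio training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_dataset <- function(labels, ratio = 0.7, seed) {
  if (ratio <= 0 || ratio >= 1)
    stop("split_dataset: ratio must be strictly between 0 and 1")
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("split_dataset: class '", small[1],
         "' has fewer than 2 members and cannot be stratified")
  with_seed(seed, {
    train <- integer()
    for (cl in sort(names(tab))) {
      idx <- which(labels == cl)
      n_tr <- min(max(round(length(idx) * ratio), 1), length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Default hyperparameter search bounds
#' @return named list of bounds for eta (log-uniform), gamma, max_depth,
#'   min_child_weight, subsample and nrounds.
#' @export
default_search_bounds <- function() {
  list(eta = c(0.01, 0.3), gamma = c(0, 5), max_depth = c(2L, 10L),
       min_child_weight = c(1, 10), subsample = c(0.5, 1),
       nrounds = c(50L, 1000L))
}

sample_hyperparameters <- function(bounds) {
  list(
    eta = exp(stats::runif(1, log(bounds$eta[1]), log(bounds$eta[2]))),
    gamma = stats::runif(1, bounds$gamma[1], bounds$gamma[2]),
    max_depth = sample(bounds$max_depth[1]:bounds$max_depth[2], 1),
    min_child_weight = stats::runif(1, bounds$min_child_weight[1],
                                    bounds$min_child_weight[2]),
    subsample = stats::runif(1, bounds$subsample[1], bounds$subsample[2]),
    nrounds = sample(bounds$nrounds[1]:bounds$nrounds[2], 1))
}

feature_values <- function(x) {
  if (inherits(x, "cnv_feature_matrix")) x$values else as.matrix(x)
}

encode_labels <- function(labels, task) {
  labels <- as.character(labels)
  bad <- !labels %in% task$classes
  if (any(bad))
    stop("label outside task encoding: ", labels[bad][1])
  match(labels, task$classes) - 1L
}

xgb_fit <- function(x, y_enc, task, hp, seed) {
  params <- list(eta = hp$eta, gamma = hp$gamma, max_depth = hp$max_depth,
                 min_child_weight = hp$min_child_weight,
                 subsample = hp$subsample, nthread = 1, seed = seed)
  if (task$task == "binary") {
    params$objective <- "binary:logistic"
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- length(task$classes)
  }
  dtrain <- xgboost::xgb.DMatrix(x, label = y_enc, nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = hp$nrounds,
                     verbose = 0)
}

xgb_probs <- function(booster, x, task) {
  p <- predict(booster, x)
  probs <- if (task$task == "binary") cbind(1 - p, p)
           else matrix(p, ncol = length(task$classes))
  colnames(probs) <- task$classes
  probs
}

mean_ovr_auc <- function(probs, labels, classes) {
  present <- intersect(classes, unique(labels))
  aucs <- vapply(present, function(cl)
    roc_auc(probs[, cl], as.integer(labels == cl)), numeric(1))
  mean(aucs)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune hyperparameters by seeded random search under cross-validation
#'
#' Samples \code{n_trials} configurations from the declared bounds and
#' returns the one maximizing the mean cross-validated objective (binary:
#' AUC of the pathogenic probability; five-tier: mean one-vs-rest AUC over
#' classes). Folds are stratified by class; the whole search is
#' reproducible for a fixed seed.
#'
#' @param x feature matrix (imputed) or \code{cnv_feature_matrix}.
#' @param labels class label per row.
#' @param task a \code{cnv_task}.
#' @param n_trials number of sampled configurations (>= 1).
#' @param cv_folds fold count (must not exceed the smallest class size).
#' @param seed integer RNG seed.
#' @param bounds search bounds, see \code{default_search_bounds}.
#' @return best hyperparameters (list, class \code{cnv_hyperparams}) with
#'   attribute \code{cv_auc}.
#' @export
tune_hyperparameters <- function(x, labels, task, n_trials = 20,
                                 cv_folds = 10, seed,
                                 bounds = default_search_bounds()) {
  stopifnot(n_trials >= 1)
  x <- feature_values(x)
  labels <- as.character(labels)
  if (cv_folds > min(table(labels)))
    stop("tune_hyperparameters: cv_folds exceeds the smallest class size")
  y_enc <- encode_labels(labels, task)
  with_seed(seed, {
    fold <- stratified_folds(labels, cv_folds)
    best <- NULL; best_auc <- -Inf
    for (trial in seq_len(n_trials)) {
      hp <- sample_hyperparameters(bounds)
      fold_auc <- vapply(seq_len(cv_folds), function(k) {
        tr <- fold != k
        booster <- xgb_fit(x[tr, , drop = FALSE], y_enc[tr], task, hp,
                           seed = seed + trial)
        probs <- xgb_probs(booster, x[!tr, , drop = FALSE], task)
        mean_ovr_auc(probs, labels[!tr], task$classes)
      }, numeric(1))
      m <- mean(fold_auc)
      if (m > best_auc) { best_auc <- m; best <- hp }
    }
    class(best) <- "cnv_hyperparams"
    attr(best, "cv_auc") <- best_auc
    best
  })
}

#' Train a gradient-boosted pathogenicity classifier
#'
#' Fits an XGBoost ensemble (binary logistic or multiclass softprob) with
#' the given hyperparameters. Training is deterministic given the seed. The
#' model stores the imputation medians and a registry fingerprint so it can
#' only be applied to compatibly annotated matrices.
#'
#' @param x imputed \code{cnv_feature_matrix} (or plain numeric matrix with
#'   feature column names; medians then taken from \code{medians}).
#' @param labels class label per row, within the task's class alphabet.
#' @param hp hyperparameters (list with eta, gamma, max_depth,
#'   min_child_weight, subsample, nrounds).
#' @param task a \code{cnv_task}.
#' @param seed integer training seed.
#' @param medians optional named vector of imputation medians (taken from
#'   the feature matrix if fitted there).
#' @return list of class \code{cnv_model}.
#' @export
train_model <- function(x, labels, hp, task, seed, medians = NULL) {
  vals <- feature_values(x)
  if (anyNA(vals))
    stop("train_model: feature matrix contains missing values; impute first")
  if (inherits(x, "cnv_feature_matrix") && is.null(medians))
    medians <- x$medians
  y_enc <- encode_labels(labels, task)
  present <- task$classes[sort(unique(y_enc)) + 1L]
  if (length(present) < 2)
    stop("train_model: need at least two classes present")
  booster <- xgb_fit(vals, y_enc, task, hp, seed)
  out <- list(booster = booster, task = task, hp = hp, seed = seed,
              medians = medians,
              fingerprint = paste(colnames(vals), collapse = "|"))
  class(out) <- "cnv_model"
  out
}

#' @export
print.cnv_model <- function(x, ...) {
  cat(sprintf("CNV pathogenicity model: %s / %s CNVs, %d boosting rounds\n",
              x$task$task, x$task$cnv_type, x$hp$nrounds))
  invisible(x)
}

#' Predict pathogenicity class probabilities
#'
#' Rows with missing cells are imputed with the model's stored training
#' medians before prediction. Probabilities per row sum to 1; the reported
#' label is the argmax with ties broken toward the more pathogenic class.
#'
#' @param object a \code{cnv_model}.
#' @param newdata \code{cnv_feature_matrix} or numeric matrix with matching
#'   feature columns.
#' @param ... unused.
#' @return data.frame: record_id (if available), one probability column per
#'   class, and \code{label}.
#' @export
predict.cnv_model <- function(object, newdata, ...) {
  vals <- feature_values(newdata)
  fp <- paste(colnames(vals), collapse = "|")
  if (!identical(fp, object$fingerprint))
    stop("predict: feature columns do not match the model's registry fingerprint")
  if (anyNA(vals)) {
    if (is.null(object$medians))
      stop("predict: matrix has missing values and the model stores no medians")
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) vals[nas, j] <- object$medians[[colnames(vals)[j]]]
    }
  }
  probs <- xgb_probs(object$booster, vals, object$task)
  # ties break toward the more pathogenic class (classes ordered benign ->
  # pathogenic), hence the last index attaining the row maximum
  label <- object$task$classes[apply(probs, 1, function(p)
    max(which(p >= max(p) - 1e-12)))]
  out <- data.frame(probs, check.names = FALSE)
  out$label <- label
  if (!is.null(rownames(vals))) out <- cbind(record_id = rownames(vals), out)
  rownames(out) <- NULL
  out
}

#' Margin (log-odds / per-class raw score) output of a model
#' @param model a \code{cnv_model}.
#' @param x feature matrix (imputed).
#' @return numeric vector (binary) or matrix (multiclass) of margins.
#' @export
model_margin <- function(model, x) {
  predict(model$booster, feature_values(x), outputmargin = TRUE)
}
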