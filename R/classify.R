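# Gaussian-kernel SVM classification of metal clusters, with stratified
# tenfold cross-validation, cross-dataset transfer evaluation and the usual
# confusion-matrix metrics. Training is an in-package SMO implementation
# (src/svm.cpp); no randomness enters training itself, only the fold split.

.valid_classes <- c("ECOG", "DEPTH", "NON_ELECTRODE")

#' G-SVM configuration
#'
#' @param box_constraint soft-margin box constraint C (> 0, default 1).
#' @param kernel_scale_mode `"feature_scaled"` (default): RBF
#'   `gamma = 1 / (n_features * pooled variance)` computed on the
#'   (standardized) training matrix; `"unit"`: gamma = 1; `"value"`: kernel
#'   scale sigma given explicitly, `gamma = 1 / sigma^2`.
#' @param kernel_scale_value kernel scale sigma for mode `"value"`.
#' @param standardize standardize features to zero mean / unit variance with
#'   training-set statistics (default TRUE).
#' @param class_weighting `"none"` (default) or `"balanced"` (per-class C
#'   inversely proportional to class frequency).
#' @param seed integer seed recorded with the model (training is
#'   deterministic; the seed drives fold splits downstream).
#' @return a `gsvm_config` list.
#' @export
gsvm_config <- function(box_constraint = 1,
                        kernel_scale_mode = c("feature_scaled", "unit", "value"),
                        kernel_scale_value = NULL,
                        standardize = TRUE,
                        class_weighting = c("none", "balanced"),
                        seed = 1L) {
  kernel_scale_mode <- match.arg(kernel_scale_mode)
  class_weighting <- match.arg(class_weighting)
  if (!is.numeric(box_constraint) || box_constraint <= 0)
    stop("box_constraint must be > 0")
  if (kernel_scale_mode == "value" &&
      (is.null(kernel_scale_value) || kernel_scale_value <= 0))
    stop("kernel_scale_value must be a positive number in mode 'value'")
  structure(list(box_constraint = box_constraint,
                 kernel_scale_mode = kernel_scale_mode,
                 kernel_scale_value = kernel_scale_value,
                 standardize = isTRUE(standardize),
                 class_weighting = class_weighting,
                 multiclass = "one_vs_one",
                 seed = as.integer(seed)),
            class = "gsvm_config")
}

#' Assemble labeled feature tables into a classification dataset
#'
#' @param tables a `feature_table` or list of them; every row must carry a
#'   `true_class` label.
#' @param name dataset name (e.g. `"C1"`).
#' @param feature_names feature columns, default the six shape descriptors.
#' @return a `labeled_dataset`: feature matrix, labels, per-instance patient
#'   groups, name.
#' @export
assemble_dataset <- function(tables, name = "dataset",
                             feature_names = .feature_names) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  tabs <- lapply(tables, function(t) {
    if (any(is.na(t$true_class)))
      stop("feature table with missing true_class labels cannot be assembled")
    t
  })
  all <- do.call(rbind, lapply(tabs, as.data.frame))
  bad <- setdiff(unique(all$true_class), .valid_classes)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(all[, feature_names, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values in dataset")
  structure(list(features = X, labels = all$true_class,
                 groups = all$patient_id, name = name,
                 feature_names = feature_names),
            class = "labeled_dataset")
}

.resolve_gamma <- function(Xs, config) {
  switch(config$kernel_scale_mode,
         unit = 1,
         value = 1 / config$kernel_scale_value^2,
         feature_scaled = {
           v <- stats::var(as.vector(Xs))
           if (!is.finite(v) || v <= 0) v <- 1
           1 / (ncol(Xs) * v)
         })
}

#' Train a Gaussian-kernel SVM
#'
#' Binary or multiclass (one-vs-one voting). Deterministic given data and
#' configuration.
#'
#' @param data a `labeled_dataset` with >= 2 classes and >= 2 instances per
#'   class.
#' @param config a [gsvm_config()].
#' @return a `gsvm_classifier`.
#' @export
train_gsvm <- function(data, config = gsvm_config()) {
  if (!inherits(data, "labeled_dataset")) stop("not a labeled_dataset")
  X <- data$features
  if (any(!is.finite(X))) stop("non-finite feature values")
  classes <- sort(unique(data$labels))
  if (length(classes) < 2) stop("training requires at least 2 classes")
  if (any(table(data$labels) < 2))
    stop("training requires >= 2 instances per class")
  if (config$standardize) {
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
  } else {
    mu <- rep(0, ncol(X)); sd <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  gamma <- .resolve_gamma(Xs, config)
  cls_n <- table(data$labels)
  cw <- rep(1, length(classes)); names(cw) <- classes
  if (config$class_weighting == "balanced")
    cw <- length(data$labels) / (length(classes) * as.numeric(cls_n[classes]))
  names(cw) <- classes

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- lapply(pairs, function(p) {
    sel <- data$labels %in% p
    y <- ifelse(data$labels[sel] == p[1], 1, -1)
    Cvec <- config$box_constraint *
      ifelse(y > 0, cw[[p[1]]], cw[[p[2]]])
    fit <- .cpp_svm_train(Xs[sel, , drop = FALSE], as.double(y),
                          as.double(Cvec), gamma, 1e-3, 200)
    if (!fit$converged)
      warning("SMO hit the iteration cap for pair ",
              paste(p, collapse = "/"), "; model may be suboptimal")
    list(classes = p, sv = fit$sv, coef = fit$coef, b = fit$b)
  })
  structure(list(version = 1L, classes = classes, pair_models = models,
                 gamma = gamma, center = mu, scale = sd,
                 feature_names = data$feature_names,
                 meta = list(dataset = data$name, config = config,
                             n_instances = nrow(X), seed = config$seed)),
            class = "gsvm_classifier")
}

.predict_matrix <- function(model, X) {
  if (ncol(X) != length(model$feature_names))
    stop("feature dimension mismatch: model expects ",
         length(model$feature_names), " features, got ", ncol(X))
  if (nrow(X) == 0)
    return(data.frame(predicted_class = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  if (any(!is.finite(X))) stop("non-finite feature values")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  K <- length(model$classes)
  votes <- matrix(0, nrow(X), K, dimnames = list(NULL, model$classes))
  margin <- matrix(0, nrow(X), K, dimnames = list(NULL, model$classes))
  dec1 <- NULL
  for (pm in model$pair_models) {
    d <- .cpp_svm_decision(pm$sv, pm$coef, pm$b, model$gamma, Xs)
    win <- ifelse(d > 0, pm$classes[1], pm$classes[2])
    votes[cbind(seq_along(win), match(win, model$classes))] <-
      votes[cbind(seq_along(win), match(win, model$classes))] + 1
    margin[, pm$classes[1]] <- margin[, pm$classes[1]] + d
    margin[, pm$classes[2]] <- margin[, pm$classes[2]] - d
    if (is.null(dec1)) dec1 <- d
  }
  # winner by votes; ties broken by summed signed decision values, then by
  # class order (deterministic)
  pred <- character(nrow(X))
  score <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    w <- which(votes[i, ] == max(votes[i, ]))
    if (length(w) > 1) w <- w[which.max(margin[i, w])]
    pred[i] <- model$classes[w]
    score[i] <- if (K == 2) dec1[i] else margin[i, w] / (K - 1)
  }
  data.frame(predicted_class = pred, score = score, stringsAsFactors = FALSE)
}

#' Predict cluster classes with a trained G-SVM
#'
#' @param object a `gsvm_classifier`.
#' @param newdata a `feature_table`, `labeled_dataset`, or numeric matrix
#'   with the model's feature columns.
#' @param ... unused.
#' @return data.frame with `predicted_class` and `score` (signed decision
#'   value for binary models, mean pairwise margin of the winner otherwise).
#' @export
predict.gsvm_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) newdata$features
  else if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss)) stop("feature dimension mismatch: missing columns ",
                           paste(miss, collapse = ", "))
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else as.matrix(newdata)
  .predict_matrix(object, X)
}

#' Confusion matrix, accuracy, per-class sensitivity and specificity
#'
#' Rows of the confusion matrix are true classes, columns predicted classes.
#' Sensitivity(c) = 100 TP/(TP+FN), specificity(c) = 100 TN/(TN+FP), both in
#' the one-vs-rest sense.
#'
#' @param true_labels,predicted_labels equal-length character vectors.
#' @param class_universe class ordering for the matrix (default: sorted union).
#' @return an `evaluation_report`.
#' @export
compute_report <- function(true_labels, predicted_labels,
                           class_universe = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  if (is.null(class_universe))
    class_universe <- sort(unique(c(true_labels, predicted_labels)))
  tf <- factor(true_labels, levels = class_universe)
  pf <- factor(predicted_labels, levels = class_universe)
  if (any(is.na(tf)) || any(is.na(pf)))
    stop("labels outside the class universe")
  cm <- table(true = tf, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = length(class_universe),
               dimnames = list(true = class_universe,
                               predicted = class_universe))
  n <- sum(cm)
  rowsums <- rowSums(cm)
  pct <- sweep(cm, 1, ifelse(rowsums > 0, rowsums, 1), "/") * 100
  sens <- spec <- stats::setNames(numeric(length(class_universe)),
                                  class_universe)
  for (cl in class_universe) {
    tp <- cm[cl, cl]
    fn <- rowsums[cl] - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    sens[cl] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec[cl] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  }
  structure(list(confusion_counts = cm, confusion_percent = pct,
                 accuracy = if (n > 0) 100 * sum(diag(cm)) / n else NA_real_,
                 per_class_sensitivity = sens, per_class_specificity = spec,
                 per_fold_accuracy = NULL, n_instances = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: n = %d, accuracy = %.2f%%\n",
              x$n_instances, x$accuracy))
  cat("confusion (rows = true, %):\n")
  print(round(x$confusion_percent, 2))
  cat("sensitivity (%):", paste(sprintf("%s %.2f", names(x$per_class_sensitivity),
                                        x$per_class_sensitivity), collapse = ", "), "\n")
  invisible(x)
}

# Stratified fold assignment derived from the seed and *sorted* instance
# keys, so the split is invariant to row shuffling of the input.
.fold_assignment <- function(data, k, seed) {
  n <- length(data$labels)
  key <- paste(apply(data$features, 1, function(r)
    paste(sprintf("%.12g", r), collapse = ",")), data$groups, sep = "|")
  fold <- integer(n)
  set.seed(seed)
  for (cl in sort(unique(data$labels))) {
    idx <- which(data$labels == cl)
    idx <- idx[order(key[idx], idx)]
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.subset_dataset <- function(data, sel, cols = NULL) {
  X <- data$features[sel, , drop = FALSE]
  if (!is.null(cols)) X <- X[, cols, drop = FALSE]
  structure(list(features = X, labels = data$labels[sel],
                 groups = data$groups[sel], name = data$name,
                 feature_names = colnames(X)),
            class = "labeled_dataset")
}

#' Stratified k-fold cross-validation of the G-SVM
#'
#' The dataset is split into k stratified random folds derived from `seed`;
#' each fold is predicted by a model trained on the other k-1. The headline
#' `accuracy` is the mean of the k fold accuracies; the pooled confusion
#' matrix over all held-out predictions is also reported (with its own
#' `pooled_accuracy`).
#'
#' @param data a `labeled_dataset`.
#' @param k number of folds (default 10).
#' @param config a [gsvm_config()].
#' @param seed fold-split seed (default: `config$seed`).
#' @return an `evaluation_report` with `per_fold_accuracy` filled in.
#' @export
crossvalidate_kfold <- function(data, k = 10, config = gsvm_config(),
                                seed = config$seed) {
  if (!inherits(data, "labeled_dataset")) stop("not a labeled_dataset")
  n <- length(data$labels)
  if (!is.numeric(k) || k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of instances")
  if (any(table(data$labels) < k))
    stop("every class needs >= k instances for stratified folds")
  fold <- .fold_assignment(data, k, seed)
  truth <- pred <- character(n)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- .subset_dataset(data, fold != f)
    te <- .subset_dataset(data, fold == f)
    model <- train_gsvm(tr, config)
    p <- .predict_matrix(model, te$features)$predicted_class
    truth[fold == f] <- te$labels
    pred[fold == f] <- p
    fold_acc[f] <- 100 * mean(p == te$labels)
  }
  rep <- compute_report(truth, pred, sort(unique(data$labels)))
  rep$per_fold_accuracy <- fold_acc
  rep$pooled_accuracy <- rep$accuracy
  rep$accuracy <- mean(fold_acc)
  rep
}

#' Evaluate a trained classifier on held-out datasets
#'
#' @param model a `gsvm_classifier`.
#' @param test_sets a `labeled_dataset` or list of them; test classes must
#'   be a subset of the model's.
#' @return list with `reports` (one `evaluation_report` per set, named),
#'   `mean_accuracy` and `sd_accuracy` across sets.
#' @export
evaluate_transfer <- function(model, test_sets) {
  if (inherits(test_sets, "labeled_dataset")) test_sets <- list(test_sets)
  reports <- lapply(test_sets, function(ts) {
    extra <- setdiff(unique(ts$labels), model$classes)
    if (length(extra))
      stop("test set contains class(es) unknown to the model: ",
           paste(extra, collapse = ", "))
    p <- .predict_matrix(model, ts$features)$predicted_class
    compute_report(ts$labels, p, model$classes)
  })
  names(reports) <- vapply(test_sets, function(ts) ts$name, "")
  acc <- vapply(reports, function(r) r$accuracy, 0)
  list(reports = reports, mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc))
}

#' Cross-validated accuracy for feature subsets containing the volume
#'
#' Evaluates tenfold-CV accuracy for the volume-only subset, volume paired
#' with each other feature, and the full feature set, reusing one fold split
#' for all subsets so accuracies are directly comparable.
#'
#' @param data a `labeled_dataset` over the six standard features.
#' @param config a [gsvm_config()].
#' @param seed fold-split seed.
#' @param k folds (default 10).
#' @param subsets optional list of character vectors (each must contain
#'   `"volume"`); default as described.
#' @return data.frame with `subset`, `n_features`, `cv_accuracy`,
#'   `pooled_accuracy`.
#' @export
feature_subset_ablation <- function(data, config = gsvm_config(),
                                    seed = config$seed, k = 10,
                                    subsets = NULL) {
  if (!inherits(data, "labeled_dataset")) stop("not a labeled_dataset")
  fn <- data$feature_names
  if (!"volume" %in% fn) stop("dataset lacks the volume feature")
  if (is.null(subsets)) {
    others <- setdiff(fn, "volume")
    subsets <- c(list("volume"),
                 lapply(others, function(f) c("volume", f)),
                 list(fn))
  }
  if (!all(vapply(subsets, function(s) "volume" %in% s, TRUE)))
    stop("every ablation subset must contain the volume feature")
  subsets <- subsets[!duplicated(vapply(subsets, paste, "", collapse = "+"))]
  fold <- .fold_assignment(data, k, seed)
  res <- lapply(subsets, function(cols) {
    truth <- pred <- character(length(data$labels))
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- .subset_dataset(data, fold != f, cols)
      te <- .subset_dataset(data, fold == f, cols)
      model <- train_gsvm(tr, config)
      p <- .predict_matrix(model, te$features)$predicted_class
      truth[fold == f] <- te$labels
      pred[fold == f] <- p
      fold_acc[f] <- 100 * mean(p == te$labels)
    }
    data.frame(subset = paste(cols, collapse = "+"),
               n_features = length(cols),
               cv_accuracy = mean(fold_acc),
               pooled_accuracy = 100 * mean(pred == truth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Persist / restore a trained classifier
#'
#' The model is stored as a single versioned RDS file.
#'
#' @param model a `gsvm_classifier`.
#' @param path file path.
#' @return `path` (save) or the restored `gsvm_classifier` (load).
#' @export
save_classifier <- function(model, path) {
  if (!inherits(model, "gsvm_classifier")) stop("not a gsvm_classifier")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "gsvm_classifier") || is.null(model$version))
    stop("not a saved gsvm_classifier: ", path)
  model
}
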