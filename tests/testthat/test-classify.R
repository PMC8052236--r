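test_that("assemble_dataset concatenates labeled tables and rejects unlabeled", {
  m <- array(FALSE, c(6, 6, 6)); m[2:3, 2:3, 2:3] <- TRUE; m[5, 5, 5] <- TRUE
  t1 <- compute_feature_table(labeling_from_mask(m), patient_id = "a")
  t1$true_class <- c("ECOG", "NON_ELECTRODE")
  t2 <- t1; t2$patient_id <- "b"
  ds <- assemble_dataset(list(t1, t2), "combo")
  expect_equal(length(ds$labels), 4)
  expect_equal(ds$groups, c("a", "a", "b", "b"))
  expect_equal(ncol(ds$features), 6)

  single <- assemble_dataset(t1, "one")
  expect_equal(length(single$labels), 2)

  t3 <- t1; t3$true_class <- NA_character_
  expect_error(assemble_dataset(list(t3), "x"), "true_class")
  t4 <- t1; t4$true_class <- c("ECOG", "WIRE")
  expect_error(assemble_dataset(list(t4), "x"), "unknown class")
})

test_that("G-SVM separates blobs; RBF beats a linear control on XOR", {
  ds <- blobs_dataset()
  model <- train_gsvm(ds, gsvm_config())
  pred <- predict(model, ds$features)
  expect_equal(mean(pred$predicted_class == ds$labels), 1)

  xo <- xor_dataset()
  mx <- train_gsvm(xo, gsvm_config())
  acc_rbf <- mean(predict(mx, xo$features)$predicted_class == xo$labels)
  expect_gt(acc_rbf, 0.95)
  # linear control: logistic regression cannot represent XOR
  lin <- stats::glm((xo$labels == "ECOG") ~ xo$features, family = "binomial")
  acc_lin <- mean((stats::fitted(lin) > 0.5) == (xo$labels == "ECOG"))
  expect_lte(acc_lin, 0.75)
})

test_that("training argument errors", {
  ds <- blobs_dataset()
  one <- ds; one$labels <- rep("ECOG", length(ds$labels))
  expect_error(train_gsvm(one), "2 classes")
  bad <- ds; bad$features[1, 1] <- NaN
  expect_error(train_gsvm(bad), "finite")
  expect_error(gsvm_config(box_constraint = -1), "box_constraint")
})

test_that("predict: training labels recovered, empty input, dim mismatch", {
  ds <- blobs_dataset()
  model <- train_gsvm(ds)
  expect_equal(predict(model, ds$features)$predicted_class, ds$labels)
  empty <- predict(model, ds$features[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_error(predict(model, ds$features[, 1, drop = FALSE]), "mismatch")
})

test_that("G-SVM agrees with scikit-learn SVC on a fixed dataset", {
  ds <- blobs_dataset(n_per = 30, sep = 3, seed = 9)  # overlapping classes
  cfg <- gsvm_config(kernel_scale_mode = "unit", standardize = FALSE)
  model <- train_gsvm(ds, cfg)
  pred <- predict(model, ds$features)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(ds$features,
                              y = as.integer(ds$labels == "ECOG")),
                   csv, row.names = FALSE)
  script <- paste(
    "import json, numpy as np",
    "from sklearn.svm import SVC",
    sprintf("d = np.genfromtxt('%s', delimiter=',', skip_header=1)", csv),
    "X, y = d[:, :2], d[:, 2]",
    "m = SVC(C=1.0, kernel='rbf', gamma=1.0).fit(X, y)",
    "dec = m.decision_function(X)",
    "print(json.dumps({'pred': m.predict(X).tolist(),",
    "                  'dec': dec.tolist()}))", sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  res <- jsonlite::fromJSON(out[length(out)])
  skl_pred <- ifelse(res$pred == 1, "ECOG", "NON_ELECTRODE")
  # same dual optimum: decision values coincide, predictions agree away
  # from the numerical boundary
  expect_lt(max(abs(pred$score - res$dec)), 2e-2)
  sure <- abs(res$dec) > 0.05
  expect_equal(pred$predicted_class[sure], skl_pred[sure])
  unlink(csv)
})

test_that("compute_report reproduces hand counts and edge cases", {
  r <- compute_report(c("E", "E", "E", "N"), c("E", "E", "N", "N"),
                      c("E", "N"))
  expect_equal(r$accuracy, 75)
  expect_equal(unname(r$per_class_sensitivity["E"]), 100 * 2 / 3)
  expect_equal(unname(r$per_class_specificity["E"]), 100)
  expect_equal(unname(r$confusion_counts["E", "N"]), 1)
  expect_equal(unname(rowSums(r$confusion_percent)), c(100, 100))

  perfect <- compute_report(rep(c("A", "B", "C"), 4), rep(c("A", "B", "C"), 4))
  expect_equal(unname(diag(perfect$confusion_percent)), rep(100, 3))

  wrong <- compute_report(c("A", "B"), c("B", "A"))
  expect_equal(wrong$accuracy, 0)
  expect_equal(unname(wrong$per_class_sensitivity), c(0, 0))

  expect_error(compute_report(c("A"), c("A", "B")), "equal length")
})

test_that("cross-validation: separable data, determinism, shuffle invariance", {
  ds <- blobs_dataset()
  r1 <- crossvalidate_kfold(ds, 10, gsvm_config(), seed = 42)
  expect_equal(r1$accuracy, 100)
  expect_equal(length(r1$per_fold_accuracy), 10)
  expect_equal(r1$pooled_accuracy,
               100 * sum(diag(r1$confusion_counts)) / r1$n_instances)

  r2 <- crossvalidate_kfold(ds, 10, gsvm_config(), seed = 42)
  expect_identical(r1$confusion_counts, r2$confusion_counts)
  expect_identical(r1$per_fold_accuracy, r2$per_fold_accuracy)

  # same seed on a row-shuffled copy: same report (folds from sorted keys)
  r3 <- crossvalidate_kfold(shuffle_dataset(ds, 5), 10, gsvm_config(),
                            seed = 42)
  expect_identical(r1$confusion_counts, r3$confusion_counts)
  expect_equal(sort(r1$per_fold_accuracy), sort(r3$per_fold_accuracy))

  expect_error(crossvalidate_kfold(ds, 0), "k must be")
  expect_error(crossvalidate_kfold(ds, 1000), "exceeds")
  tiny <- blobs_dataset(n_per = 5)
  expect_error(crossvalidate_kfold(tiny, 10), ">= k instances")
})

test_that("3-class one-vs-one training and prediction work", {
  set.seed(31)
  X <- rbind(matrix(stats::rnorm(60), ncol = 2),
             matrix(stats::rnorm(60) + 8, ncol = 2),
             cbind(stats::rnorm(30) + 8, stats::rnorm(30)))
  colnames(X) <- c("volume", "circularity")
  ds <- structure(list(features = X,
                       labels = rep(c("DEPTH", "ECOG", "NON_ELECTRODE"),
                                    each = 30),
                       groups = rep("p", 90), name = "tri",
                       feature_names = colnames(X)),
                  class = "labeled_dataset")
  model <- train_gsvm(ds)
  expect_equal(length(model$pair_models), 3)
  expect_equal(mean(predict(model, X)$predicted_class == ds$labels), 1)
  r <- crossvalidate_kfold(ds, 10, seed = 3)
  expect_gt(r$accuracy, 95)
})

test_that("transfer evaluation: self-test, identical sets, class checks", {
  ds <- blobs_dataset()
  model <- train_gsvm(ds)
  res <- evaluate_transfer(model, list(ds, ds))
  expect_equal(res$mean_accuracy, 100)
  expect_equal(res$sd_accuracy, 0)

  tri <- blobs_dataset()
  tri$labels[1] <- "DEPTH"
  expect_error(evaluate_transfer(model, tri), "unknown to the model")
})

test_that("transfer prediction does not touch test labels", {
  ds <- blobs_dataset()
  model <- train_gsvm(ds)
  blind <- ds
  blind$labels <- rep(NA_character_, length(ds$labels))
  p1 <- predict(model, blind$features)
  p2 <- predict(model, ds$features)
  expect_identical(p1, p2)
})

test_that("ablation always contains volume-only and the full set", {
  ds <- blobs_dataset()
  ab <- feature_subset_ablation(ds, gsvm_config(), seed = 11, k = 5)
  expect_true("volume" %in% ab$subset)
  expect_true(paste(ds$feature_names, collapse = "+") %in% ab$subset)
  expect_gte(nrow(ab), 2)
  expect_true(all(grepl("volume", ab$subset)))
  expect_true(all(ab$cv_accuracy[ab$subset == paste(ds$feature_names,
                                                    collapse = "+")] == 100))
  expect_error(feature_subset_ablation(ds, subsets = list(c("circularity"))),
               "volume")
})

test_that("classifier persists to a versioned file and restores", {
  ds <- blobs_dataset()
  model <- train_gsvm(ds)
  path <- tempfile(fileext = ".rds")
  save_classifier(model, path)
  back <- load_classifier(path)
  expect_identical(predict(back, ds$features), predict(model, ds$features))
  expect_equal(back$version, 1L)
  expect_error(load_classifier(tempfile()), "not found")
  unlink(path)
})
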