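test_that("label encoding maps D to -1, drops E, everything else to +1", {
  tab <- data.frame(r = 1:4, gv = 1:4, GVSD = 1:4, distAZ = 1:4,
                    label = c("C", "D", "N", "E"))
  ds <- encode_labels(list(f1 = tab))
  expect_equal(ds$y, c(1, -1, 1))
  expect_equal(nrow(ds$x), 3L)       # the E row is gone
  expect_equal(ds$group, rep("f1", 3))

  bad <- tab; bad$label[2] <- "Q"
  expect_error(encode_labels(list(f1 = bad)), "row 2")
})

test_that("training succeeds on separable toys and is reproducible", {
  x <- rbind(c(1, 1, 1, 1), c(2, 2, 2, 2), c(-1, -1, -1, -1),
             c(-2, -2, -2, -2))
  colnames(x) <- c("r", "gv", "distAZ", "GVSD")
  ds <- list(x = x, y = c(1, 1, -1, -1))
  for (algo in c("svm_linear", "svm_rbf", "knn")) {
    fit <- train_classifier(ds, training_config(algo, k = 1))
    expect_equal(predict(fit, x), ds$y, info = algo)
  }
  rf1 <- train_classifier(ds, training_config("random_forest", seed = 5))
  rf2 <- train_classifier(ds, training_config("random_forest", seed = 5))
  expect_equal(predict(rf1, x), predict(rf2, x))
  expect_error(train_classifier(list(x = x, y = rep(1, 4)),
                                training_config("svm_linear")), "class")
})

test_that("the exported linear model reproduces the trainer's predictions", {
  tab <- sample_feature_table(n = 600, dcv_fraction = 0.25, seed = 17)
  ds <- encode_labels(list(t1 = tab))
  trained <- train_classifier(ds, training_config("svm_linear"))
  model <- export_linear_model(trained)
  own <- predict(trained, ds$x)
  via_model <- ifelse(classify_table(as.data.frame(ds$x), model)$class ==
                        "CCV", 1, -1)
  expect_equal(via_model, own)
})

test_that("metric formulas evaluate exactly on closed-form cases", {
  m <- compute_metrics(c(tp = 9, fp = 1, fn = 1, tn = 89))
  expect_equal(unname(m), c(0.98, 0.9, 0.9, 0.9))
  # F is the harmonic mean: P = 1, R = 0.5 -> 2/3
  m2 <- compute_metrics(c(tp = 1, fp = 0, fn = 1, tn = 0))
  expect_equal(m2[["precision_DCV"]], 1)
  expect_equal(m2[["recall_DCV"]], 0.5)
  expect_equal(m2[["F_DCV"]], 2 / 3)
  # degenerate: no DCVs anywhere
  m3 <- compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(m3[["precision_DCV"]]))
  expect_true(is.na(m3[["recall_DCV"]]))
  expect_true(is.na(m3[["F_DCV"]]))
  expect_equal(m3[["accuracy"]], 1)
})

test_that("metrics agree with brute-force confusion counting", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    cc <- oracle_confusion(truth, pred)
    m <- compute_metrics(cc)
    expect_equal(sum(cc), n)
    p <- if (cc["tp"] + cc["fp"] > 0) cc[["tp"]] / (cc[["tp"]] + cc[["fp"]])
         else NA_real_
    expect_equal(m[["precision_DCV"]], p)
    # F lies between min and max of P and R when defined
    if (!any(is.na(m[c("precision_DCV", "recall_DCV", "F_DCV")]))) {
      expect_gte(m[["F_DCV"]], min(m[["precision_DCV"]], m[["recall_DCV"]]) - 1e-12)
      expect_lte(m[["F_DCV"]], max(m[["precision_DCV"]], m[["recall_DCV"]]) + 1e-12)
    }
  }
})

test_that("leave-one-file-out builds one fold per file and never leaks", {
  tabs <- lapply(1:4, function(i) sample_feature_table(n = 120, seed = 100 + i))
  names(tabs) <- paste0("f", 1:4)
  ev <- leave_one_file_out_cv(tabs, training_config("svm_linear"))
  expect_equal(nrow(ev$folds), 4L)
  expect_setequal(ev$folds$fold, names(tabs))
  # every row is validated exactly once
  expect_equal(sum(ev$folds$tp + ev$folds$fp + ev$folds$fn + ev$folds$tn),
               sum(vapply(tabs, nrow, integer(1))))

  # no leakage: the fold for f1 equals an independent train-on-rest run
  ds_rest <- encode_labels(tabs[-1])
  trained <- train_classifier(ds_rest, training_config("svm_linear"))
  ds_val <- encode_labels(tabs[1])
  pred <- predict(trained, ds_val$x)
  cc <- oracle_confusion(ds_val$y, pred)
  expect_equal(unlist(ev$folds[ev$folds$fold == "f1", c("tp", "fp", "fn", "tn")]),
               cc)

  expect_error(leave_one_file_out_cv(tabs[1]), "2 files")
})

test_that("identical separable files give perfect folds with zero spread", {
  base <- sample_feature_table(n = 150, dcv_fraction = 0.3, seed = 55)
  # make the classes trivially separable in r
  base$r <- ifelse(base$label == "D", 30, 5)
  tabs <- list(a = base, b = base)
  ev <- leave_one_file_out_cv(tabs, training_config("svm_linear"))
  expect_equal(unname(ev$mean[c("accuracy", "F_DCV")]), c(1, 1))
  expect_equal(unname(ev$sd[["F_DCV"]]), 0)
})

test_that("folds without dense-core vesicles are excluded from the averages", {
  with_dcv <- sample_feature_table(n = 150, dcv_fraction = 0.3, seed = 70)
  no_dcv <- sample_feature_table(n = 80, dcv_fraction = 0, seed = 71)
  tabs <- list(a = with_dcv, b = with_dcv, c = no_dcv)
  ev <- leave_one_file_out_cv(tabs, training_config("svm_linear"))
  expect_true(is.na(ev$folds$recall_DCV[ev$folds$fold == "c"]))
  expect_false(is.na(ev$mean[["recall_DCV"]]))
})
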