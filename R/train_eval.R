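# Training and evaluation machinery: label encoding, classifier training
# (linear/RBF SVM, random forest, KNN), leave-one-file-out cross-validation
# and DCV-specific metrics. DCV is the positive class of all metrics.

#' Training configuration
#'
#' @param algorithm one of `svm_linear`, `svm_rbf`, `random_forest`, `knn`.
#' @param C SVM cost (default 1).
#' @param trees random-forest tree count (10 or 1500 are the reference
#'   settings).
#' @param k KNN neighbour count (uniform weights, Euclidean metric).
#' @param seed RNG seed for stochastic learners (random-forest bootstrap).
#' @return list of class `training_config`.
#' @export
training_config <- function(algorithm = c("svm_linear", "svm_rbf",
                                          "random_forest", "knn"),
                            C = 1, trees = 10, k = 10, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(C > 0, trees >= 1, k >= 1)
  structure(list(algorithm = algorithm, C = C, trees = as.integer(trees),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "training_config")
}

#' Encode manual labels for training
#'
#' `D` (dense core) becomes -1; `E` (error) rows are removed; everything
#' else — `C` (clear core) and `N` (non-determinable) — becomes +1. The
#' source file of each row is kept as its group id for grouped
#' cross-validation.
#'
#' @param tables a feature table (data.frame with `label`) or a list of
#'   them; list names (or `source_id` attributes) become group ids.
#' @return list: `x` (feature matrix, columns r, gv, distAZ, GVSD), `y`
#'   (+1/-1), `group` (character).
#' @export
encode_labels <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(seq_along(tables), function(i) {
      sid <- attr(tables[[i]], "source_id")
      if (is.null(sid)) paste0("file", i) else sid
    }, character(1))
  xs <- list(); ys <- list(); gs <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    bad <- which(!(tab$label %in% LABEL_CODES))
    if (length(bad))
      stop("unknown label code '", tab$label[bad[1]], "' at row ", bad[1],
           " of ", nm, call. = FALSE)
    keep <- tab$label != "E"
    tab <- tab[keep, , drop = FALSE]
    xs[[nm]] <- feature_matrix(tab, MODEL_FEATURES)
    ys[[nm]] <- ifelse(tab$label == "D", -1, 1)
    gs[[nm]] <- rep(nm, nrow(tab))
  }
  list(x = do.call(rbind, xs), y = unlist(ys, use.names = FALSE),
       group = unlist(gs, use.names = FALSE))
}

#' Train a vesicle classifier
#'
#' Features are standardized with the training-set mean and SD before
#' fitting. SVMs use e1071 (`C`-classification), random forest uses
#' bootstrap resampling with probability-weighted voting, KNN uses uniform
#' weights and the Euclidean metric. For a linear SVM the fitted hyperplane
#' is exportable as a [linear_model()] via [export_linear_model()].
#'
#' @param dataset list with `x` and `y` as from [encode_labels()].
#' @param config [training_config()]
#' @return object of class `vesisort_trained` with a [predict][stats::predict]
#'   method returning +1/-1.
#' @export
train_classifier <- function(dataset, config = training_config()) {
  x <- dataset$x
  y <- dataset$y
  stopifnot(nrow(x) == length(y))
  if (config$algorithm %in% c("svm_linear", "svm_rbf") &&
      length(unique(y)) < 2)
    stop("SVM training needs at least one example of each class",
         call. = FALSE)
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  sigma[sigma == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  yf <- factor(y, levels = c(-1, 1))
  fit <- switch(config$algorithm,
    svm_linear = e1071::svm(z, yf, kernel = "linear", cost = config$C,
                            scale = FALSE),
    svm_rbf = e1071::svm(z, yf, kernel = "radial", cost = config$C,
                         scale = FALSE),
    random_forest = with_seed(config$seed,
      randomForest::randomForest(z, yf, ntree = config$trees,
                                 replace = TRUE)),
    knn = list(train = z, cl = yf, k = config$k))
  structure(list(algorithm = config$algorithm, fit = fit, mu = mu,
                 sigma = sigma, config = config),
            class = "vesisort_trained")
}

#' @export
predict.vesisort_trained <- function(object, newdata, ...) {
  x <- feature_matrix(newdata, MODEL_FEATURES)
  z <- sweep(sweep(x, 2, object$mu), 2, object$sigma, "/")
  pred <- switch(object$algorithm,
    svm_linear = ,
    svm_rbf = as.numeric(as.character(predict(object$fit, z))),
    random_forest = {
      # probability-weighted vote: class with highest mean tree probability
      pr <- predict(object$fit, z, type = "prob")
      as.numeric(colnames(pr)[max.col(pr, ties.method = "first")])
    },
    knn = as.numeric(as.character(
      class::knn(object$fit$train, z, object$fit$cl, k = object$fit$k))))
  pred
}

#' Export a trained linear SVM as a standalone linear model
#'
#' Recovers the hyperplane weights `w` and constant `b` of a trained linear
#' SVM, oriented so that a positive margin means clear core (+1), and
#' packages them with the training-set standardization constants: the
#' hand-off from trainer to the shipped-classifier format.
#'
#' @param trained `vesisort_trained` with `algorithm = "svm_linear"`.
#' @return [linear_model()]
#' @export
export_linear_model <- function(trained) {
  stopifnot(inherits(trained, "vesisort_trained"),
            trained$algorithm == "svm_linear")
  fit <- trained$fit
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- fit$rho  # decision value = w z - rho
  # align the sign so that a positive margin means CCV (+1): compare the
  # hyperplane's side with the fitted model's own predictions on its SVs
  sv_pred <- as.numeric(as.character(predict(fit, fit$SV)))
  sv_margin <- drop(fit$SV %*% w) - b
  if (mean((sv_margin > 0) == (sv_pred > 0)) < 0.5) {
    w <- -w
    b <- -b
  }
  linear_model(mu = trained$mu, sigma = trained$sigma,
               w = w[MODEL_FEATURES], b = b)
}

#' DCV-specific performance metrics
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F = 2 P R / (P + R)`, `accuracy = (tp + tn) / total`, with dense-core as
#' the positive class. A metric whose denominator is zero is `NA`
#' (undefined) and is excluded from fold averages.
#'
#' @param counts named vector or list with `tp`, `fp`, `fn`, `tn`.
#' @return named numeric: `accuracy`, `precision_DCV`, `recall_DCV`,
#'   `F_DCV`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  total <- tp + fp + fn + tn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && (p + r) > 0) 2 * p * r / (p + r)
       else NA_real_
  c(accuracy = acc, precision_DCV = p, recall_DCV = r, F_DCV = f)
}

confusion_counts <- function(truth, pred) {
  # positive class: DCV = -1
  c(tp = sum(truth == -1 & pred == -1),
    fp = sum(truth == 1 & pred == -1),
    fn = sum(truth == -1 & pred == 1),
    tn = sum(truth == 1 & pred == 1))
}

#' Leave-one-file-out cross-validation
#'
#' One fold per input file: that file's rows are the validation set, all
#' other files are concatenated as training data. Standardization constants
#' are computed on the training folds only. The report aggregates the
#' per-fold metrics as mean +/- sample SD (n - 1); undefined metrics (e.g.
#' a validation file without dense-core vesicles) are excluded from the
#' averages and listed in the report.
#'
#' @param tables named list of raw feature tables (with `label` codes).
#' @param config [training_config()]
#' @return object of class `vesisort_eval`: `folds` (data.frame of per-fold
#'   counts and metrics), `mean`, `sd`.
#' @export
leave_one_file_out_cv <- function(tables, config = training_config()) {
  if (length(tables) < 2)
    stop("grouped cross-validation needs at least 2 files", call. = FALSE)
  ds <- encode_labels(tables)
  groups <- unique(ds$group)
  folds <- lapply(groups, function(g) {
    tr <- ds$group != g
    trained <- train_classifier(list(x = ds$x[tr, , drop = FALSE],
                                     y = ds$y[tr]), config)
    pred <- predict(trained, ds$x[!tr, , drop = FALSE])
    cc <- confusion_counts(ds$y[!tr], pred)
    met <- compute_metrics(cc)
    data.frame(fold = g, t(cc), t(met))
  })
  folds <- do.call(rbind, folds)
  metric_cols <- c("accuracy", "precision_DCV", "recall_DCV", "F_DCV")
  mean_ <- vapply(folds[metric_cols], mean, numeric(1), na.rm = TRUE)
  sd_ <- vapply(folds[metric_cols], stats::sd, numeric(1), na.rm = TRUE)
  structure(list(folds = folds, mean = mean_, sd = sd_,
                 algorithm = config$algorithm),
            class = "vesisort_eval")
}

#' @export
print.vesisort_eval <- function(x, ...) {
  cat("leave-one-file-out cross-validation (", x$algorithm, ", ",
      nrow(x$folds), " folds)\n", sep = "")
  for (m in names(x$mean))
    cat(sprintf("  %-14s %.3f +/- %.3f\n", m, x$mean[[m]], x$sd[[m]]))
  na_folds <- x$folds$fold[apply(is.na(x$folds), 1, any)]
  if (length(na_folds))
    cat("  folds with undefined metrics (excluded from averages):",
        paste(na_folds, collapse = ", "), "\n")
  invisible(x)
}
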