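# The shipped standardized linear decision rule for clear-core vs dense-core
# vesicles, plus application of arbitrary linear models to feature tables.
#
# The decision hyperplane in standardized feature space (order r, gv,
# distAZ, GVSD) is
#     -4.36 = -1.69 r + 1.65 gv - 0.76 distAZ + 1.21 GVSD ,
# so the signed margin is m = sum(w z) - b with b = -4.36; m > 0 lies on the
# clear-core side. The intercept is folded into the margin (the printed
# hyperplane is the authoritative form of the rule). gv enters in display
# polarity (dark = low): the positive gv weight rewards the bright lumen of
# clear-core vesicles, consistent with the signs of the other weights and
# with the sign a classifier retrained on phantoms recovers.

MODEL_FEATURES <- c("r", "gv", "distAZ", "GVSD")

#' Construct a standardized linear classifier model
#'
#' @param mu,sigma standardization means and SDs, in feature order
#'   (r, gv, distAZ, GVSD); all sigma must be positive.
#' @param w hyperplane weights (same order).
#' @param b hyperplane constant: the boundary satisfies `sum(w z) = b`.
#' @param gv_offset_threshold reference gv level for the per-tomogram gv
#'   offset (see [apply_gv_offset()]); `NA` disables the offset.
#' @return object of class `vesisort_model`.
#' @export
linear_model <- function(mu, sigma, w, b, gv_offset_threshold = NA_real_) {
  stopifnot(length(mu) == 4, length(sigma) == 4, length(w) == 4,
            length(b) == 1)
  if (any(sigma <= 0)) stop("all standardization SDs must be > 0",
                            call. = FALSE)
  structure(list(features = MODEL_FEATURES,
                 mu = setNames(as.numeric(mu), MODEL_FEATURES),
                 sigma = setNames(as.numeric(sigma), MODEL_FEATURES),
                 w = setNames(as.numeric(w), MODEL_FEATURES),
                 b = as.numeric(b),
                 gv_offset_threshold = as.numeric(gv_offset_threshold)),
            class = "vesisort_model")
}

#' The shipped pre-trained linear classifier
#'
#' Standardization constants and hyperplane of the published linear SVM:
#' means (10.4, 129.1, 259.1, 5.9), SDs (3.1, 4.7, 118.5, 1.7), weights
#' (-1.69, 1.65, -0.76, 1.21) for (r, gv, distAZ, GVSD), constant -4.36.
#'
#' @return [linear_model()]
#' @export
default_model <- function() {
  linear_model(mu = c(10.4, 129.1, 259.1, 5.9),
               sigma = c(3.1, 4.7, 118.5, 1.7),
               w = c(-1.69, 1.65, -0.76, 1.21),
               b = -4.36)
}

#' @export
print.vesisort_model <- function(x, ...) {
  cat("vesisort linear classifier (features:",
      paste(x$features, collapse = ", "), ")\n")
  m <- rbind(mean = x$mu, sd = x$sigma, weight = x$w)
  colnames(m) <- x$features
  print(m)
  cat("hyperplane constant b =", x$b, "(margin m = sum(w z) - b; m > 0 -> CCV)\n")
  invisible(x)
}

#' Standardize raw features
#'
#' `z = (x - mu) / sigma`, per feature, in the model's feature order.
#'
#' @param x numeric vector (length 4) or matrix / data.frame with columns
#'   `r`, `gv`, `distAZ`, `GVSD` (any order; matched by name if named).
#' @param model [linear_model()]
#' @return standardized matrix with columns in model feature order.
#' @export
standardize <- function(x, model = default_model()) {
  z <- feature_matrix(x, model$features)
  sweep(sweep(z, 2, model$mu), 2, model$sigma, "/")
}

#' Invert the standardization
#'
#' @param z standardized matrix (model feature order).
#' @inheritParams standardize
#' @return raw-feature matrix.
#' @export
unstandardize <- function(z, model = default_model()) {
  z <- feature_matrix(z, model$features)
  sweep(sweep(z, 2, model$sigma, "*"), 2, model$mu, "+")
}

feature_matrix <- function(x, features) {
  if (is.data.frame(x)) {
    missing <- setdiff(features, names(x))
    if (length(missing))
      stop("missing feature column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    x <- as.matrix(x[, features])
  } else if (is.null(dim(x))) {
    if (length(x) != length(features))
      stop("expected ", length(features), " features", call. = FALSE)
    if (!is.null(names(x)) && setequal(names(x), features))
      x <- x[features]
    x <- matrix(x, nrow = 1, dimnames = list(NULL, features))
  } else {
    if (ncol(x) != length(features))
      stop("expected ", length(features), " feature columns", call. = FALSE)
    if (!is.null(colnames(x)) && setequal(colnames(x), features))
      x <- x[, features, drop = FALSE]
    colnames(x) <- features
  }
  storage.mode(x) <- "double"
  x
}

#' Signed decision margin
#'
#' `m = sum(w z) - b`; `m = 0` exactly on the hyperplane, `m > 0` on the
#' clear-core side.
#'
#' @param z standardized features (vector, matrix or data.frame).
#' @inheritParams standardize
#' @return numeric margin(s).
#' @export
decision_margin <- function(z, model = default_model()) {
  z <- feature_matrix(z, model$features)
  as.numeric(z %*% model$w - model$b)
}

#' Classify a feature table
#'
#' Applies the gv offset (if the model carries a threshold), standardizes,
#' computes the margin and assigns CCV iff `m >= 0` (ties go to the majority
#' class, CCV).
#'
#' @param table feature table with columns `r`, `gv`, `distAZ`, `GVSD`.
#' @param model [linear_model()]
#' @return `table` with added columns `margin` and `class`; attribute
#'   `counts` holds the per-class counts.
#' @export
classify_table <- function(table, model = default_model()) {
  required <- MODEL_FEATURES
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols))
    stop("feature table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(table) > 0) {
    bad <- which(!stats::complete.cases(table[, required]))
    if (length(bad))
      stop("missing feature value(s) for vesicle row(s) ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tab <- apply_gv_offset(table, model$gv_offset_threshold)
  if (nrow(tab) == 0L) {
    tab$margin <- numeric(0)
    tab$class <- character(0)
    attr(tab, "counts") <- c(CCV = 0L, DCV = 0L)
    return(tab)
  }
  z <- standardize(tab, model)
  m <- decision_margin(z, model)
  tab$margin <- m
  tab$class <- ifelse(m >= 0, "CCV", "DCV")
  attr(tab, "counts") <- c(CCV = sum(tab$class == "CCV"),
                           DCV = sum(tab$class == "DCV"))
  tab
}

#' Write / read a classifier model as YAML
#'
#' @param model [linear_model()]
#' @param path YAML file.
#' @return `path` / the model.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(list(features = model$features,
                        mu = as.numeric(model$mu),
                        sigma = as.numeric(model$sigma),
                        w = as.numeric(model$w), b = model$b,
                        gv_offset_threshold = model$gv_offset_threshold),
                   path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (!identical(as.character(y$features), MODEL_FEATURES))
    stop("model file must use feature order ",
         paste(MODEL_FEATURES, collapse = ", "), call. = FALSE)
  thr <- y$gv_offset_threshold
  linear_model(y$mu, y$sigma, y$w, y$b,
               gv_offset_threshold = if (is.null(thr)) NA_real_ else thr)
}
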