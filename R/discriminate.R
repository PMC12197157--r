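# PLS-DA and SVM-DA discrimination of tissue classes from optical features,
# with calibration / cross-validation accuracy reporting.

#' Fit a PLS-DA classifier
#'
#' Partial least squares discriminant analysis: latent-variable regression
#' on class-coded responses, class decided by the largest predicted code.
#' Deterministic given the feature matrix.
#'
#' @param features A [feature_matrix()].
#' @param n_components Number of latent components (default 2, capped at
#'   the feature count).
#' @return A `tuber_classifier` with a `predict` method.
#' @export
fit_plsda <- function(features, n_components = 2) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$x
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant feature column: PLS-DA undefined")
  ncomp <- min(n_components, ncol(x))
  fit <- mixOmics::plsda(x, features$labels, ncomp = ncomp)
  structure(list(kind = "plsda", fit = fit, levels = levels(features$labels),
                 n_components = ncomp, feature_kind = features$kind),
            class = "tuber_classifier")
}

#' Fit an SVM-DA classifier
#'
#' Soft-margin support vector machine, RBF kernel by default with `C = 1`
#' and `gamma = 1 / (p * var)` computed on the standardized training
#' features.  Deterministic given the feature matrix and parameters.
#'
#' @param features A [feature_matrix()].
#' @param kernel `"radial"` or `"linear"`.
#' @param cost Soft-margin cost C.
#' @param gamma RBF width; default `1 / (p * var(scaled features))`.
#' @return A `tuber_classifier`.
#' @export
fit_svmda <- function(features, kernel = c("radial", "linear"), cost = 1,
                      gamma = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  kernel <- match.arg(kernel)
  x <- features$x
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant feature column: SVM-DA undefined")
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  xs <- scale(x, ctr, scl)
  if (is.null(gamma)) gamma <- 1 / (ncol(xs) * stats::var(as.vector(xs)))
  fit <- e1071::svm(xs, features$labels, kernel = kernel, cost = cost,
                    gamma = gamma, scale = FALSE)
  structure(list(kind = "svmda", fit = fit, center = ctr, scale = scl,
                 levels = levels(features$labels),
                 feature_kind = features$kind),
            class = "tuber_classifier")
}

#' @export
predict.tuber_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (object$kind == "plsda") {
    colnames(newdata) <- colnames(object$fit$X)
    p <- predict(object$fit, newdata, dist = "max.dist")
    factor(p$class$max.dist[, object$n_components], levels = object$levels)
  } else {
    xs <- scale(newdata, object$center, object$scale)
    factor(as.character(predict(object$fit, xs)), levels = object$levels)
  }
}

.class_accuracy <- function(truth, pred) {
  lv <- levels(truth)
  per <- vapply(lv, function(l) 100 * mean(pred[truth == l] == l), 0)
  n <- as.numeric(table(truth)[lv])
  overall <- sum(per * n) / sum(n)
  list(per_class = per, overall = overall, n = n)
}

#' Evaluate a discriminant model with a calibration / cross-validation split
#'
#' Splits the samples into a stratified 70:30 calibration / held-out
#' cross-validation partition (or k-fold when `folds > 1`), fits the model
#' on the calibration set and reports per-class and overall accuracy on both
#' partitions.  Overall accuracy is the class-size-weighted mean of the
#' per-class accuracies.  Fixed seed gives an identical report.
#'
#' @param model `"plsda"` or `"svmda"`.
#' @param features A [feature_matrix()].
#' @param calibration_fraction Calibration share of each class (default 0.7).
#' @param folds 1 for a single held-out split (default); k > 1 for
#'   stratified k-fold cross-validation (calibration metrics then average
#'   the training folds).
#' @param seed Integer seed for the partition.
#' @param ... Passed to [fit_plsda()] / [fit_svmda()].
#' @return A `classification_report`.
#' @export
evaluate_discrimination <- function(model = c("svmda", "plsda"), features,
                                    calibration_fraction = 0.7, folds = 1,
                                    seed = 1, ...) {
  model <- match.arg(model)
  stopifnot(inherits(features, "feature_matrix"))
  y <- features$labels
  fitter <- if (model == "plsda") fit_plsda else fit_svmda
  idx_by_class <- split(seq_along(y), y)

  if (folds == 1) {
    assign_cal <- with_local_seed(seed, {
      unlist(lapply(idx_by_class, function(ix)
        sample(ix, round(calibration_fraction * length(ix)))))
    })
    cal <- sort(assign_cal); cv <- setdiff(seq_along(y), cal)
    fcal <- feature_matrix(features$x[cal, , drop = FALSE], y[cal],
                           features$kind)
    clf <- fitter(fcal, ...)
    acc_cal <- .class_accuracy(y[cal], predict(clf, features$x[cal, , drop = FALSE]))
    acc_cv <- .class_accuracy(y[cv], predict(clf, features$x[cv, , drop = FALSE]))
    fold_assign <- integer(length(y)); fold_assign[cv] <- 1L
  } else {
    fold_assign <- with_local_seed(seed, {
      fa <- integer(length(y))
      for (ix in idx_by_class)
        fa[sample(ix)] <- rep_len(seq_len(folds), length(ix))
      fa
    })
    pred_cv <- factor(rep(NA_character_, length(y)), levels = levels(y))
    cal_accs <- list()
    for (f in seq_len(folds)) {
      tr <- which(fold_assign != f); te <- which(fold_assign == f)
      ftr <- feature_matrix(features$x[tr, , drop = FALSE], y[tr],
                            features$kind)
      clf <- fitter(ftr, ...)
      pred_cv[te] <- predict(clf, features$x[te, , drop = FALSE])
      cal_accs[[f]] <- .class_accuracy(y[tr],
                                       predict(clf, features$x[tr, , drop = FALSE]))
    }
    acc_cv <- .class_accuracy(y, pred_cv)
    per <- Reduce(`+`, lapply(cal_accs, `[[`, "per_class")) / folds
    acc_cal <- list(per_class = per,
                    overall = mean(vapply(cal_accs, `[[`, 0, "overall")),
                    n = as.numeric(table(y)))
  }

  structure(list(
    model = model, feature_kind = features$kind,
    calibration = list(per_class = acc_cal$per_class,
                       overall = acc_cal$overall),
    cross_validation = list(per_class = acc_cv$per_class,
                            overall = acc_cv$overall),
    folds = folds, fold_assignments = fold_assign, seed = seed,
    classes = levels(y)),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%s on %s features\n", toupper(x$model), x$feature_kind))
  fmt <- function(a) paste(
    paste(sprintf("%s %.2f%%", names(a$per_class), a$per_class),
          collapse = " | "),
    sprintf("| overall %.2f%%", a$overall))
  cat("  calibration      :", fmt(x$calibration), "\n")
  cat("  cross-validation :", fmt(x$cross_validation), "\n")
  invisible(x)
}

#' Classification report as a flat data frame (Table-style layout)
#'
#' @param report A `classification_report`.
#' @return One-row data frame with per-class and overall accuracies for the
#'   calibration and cross-validation sets.
#' @export
report_as_row <- function(report) {
  cal <- report$calibration; cv <- report$cross_validation
  out <- data.frame(model = report$model, features = report$feature_kind)
  for (cl in report$classes) {
    out[[paste0("cal_", cl)]] <- cal$per_class[[cl]]
  }
  out$cal_overall <- cal$overall
  for (cl in report$classes) {
    out[[paste0("cv_", cl)]] <- cv$per_class[[cl]]
  }
  out$cv_overall <- cv$overall
  out
}
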