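# IC50 binarization, the SVR/SVM back-ends (e1071 behind the package
# surface), leave-one-out cross validation, and the evaluation reports.

#' Binarize IC50 activities against a cutoff
#'
#' A compound is labeled active when its IC50 is less than or equal to the
#' cutoff, i.e. at least as potent as the positive control whose IC50
#' defines the threshold (boundary convention: equality is active).
#' Compounds with missing IC50 for the cell line are excluded rather than
#' imputed.
#'
#' @param library A `bq_library`.
#' @param cell_line Cell-line name (one of `library$cell_lines`).
#' @param cutoff Positive IC50 threshold in the same units as the table
#'   (ug/mL).
#' @return A `bq_labeling`: list with `labels` (named logical, NA =
#'   excluded), `cutoff`, `cell_line`, `excluded` ids.
#' @export
binarize <- function(library, cell_line, cutoff) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (!cell_line %in% library$cell_lines)
    stop("unknown cell line: ", cell_line, call. = FALSE)
  ic50 <- activity_matrix(library)[, cell_line]
  if (all(is.na(ic50)))
    stop("no compound has activity for cell line ", cell_line, call. = FALSE)
  labels <- ic50 <= cutoff
  present <- labels[!is.na(labels)]
  if (all(present) || all(!present))
    warning("single-class labeling for ", cell_line,
            " at cutoff ", cutoff, call. = FALSE)
  structure(list(labels = labels, cutoff = cutoff, cell_line = cell_line,
                 excluded = names(labels)[is.na(labels)]),
            class = "bq_labeling")
}

#' SVR configuration
#' @param gamma RBF kernel width; default `NULL` means 1/n_features.
#' @param cost Soft-margin cost (default 1).
#' @param epsilon Epsilon-insensitivity of the loss (default 0.1).
#' @param seed Unused by the deterministic solver; kept for the run manifest.
#' @return A list of class `bq_svr_config`.
#' @export
svr_config <- function(gamma = NULL, cost = 1, epsilon = 0.1, seed = 1L) {
  stopifnot(cost > 0, epsilon > 0)
  structure(list(gamma = gamma, cost = cost, epsilon = epsilon,
                 seed = as.integer(seed), kernel = "radial"),
            class = "bq_svr_config")
}

#' SVM classification configuration
#' @inheritParams svr_config
#' @return A list of class `bq_svm_config`.
#' @export
svm_config <- function(gamma = NULL, cost = 1, seed = 1L) {
  stopifnot(cost > 0)
  structure(list(gamma = gamma, cost = cost, seed = as.integer(seed),
                 kernel = "radial"), class = "bq_svm_config")
}

#' Fit epsilon-insensitive support vector regression (RBF kernel)
#'
#' A constant response (zero variance) yields a constant predictor rather
#' than an error, matching the degenerate-input contract.
#'
#' @param X Numeric training matrix.
#' @param y Numeric response.
#' @param config A [svr_config()].
#' @return A `bq_svr` model.
#' @export
fit_svr <- function(X, y, config = svr_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (stats::sd(y) == 0)
    return(structure(list(constant = y[1]), class = c("bq_const", "bq_svr")))
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
  fit <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = config$cost, epsilon = config$epsilon,
                    scale = apply(X, 2, stats::sd) > 0)
  structure(list(fit = fit), class = "bq_svr")
}

#' @export
predict.bq_svr <- function(object, newdata, ...) {
  if (inherits(object, "bq_const"))
    return(rep(object$constant, nrow(as.matrix(newdata))))
  unname(stats::predict(object$fit, as.matrix(newdata)))
}

#' Fit a soft-margin RBF support vector classifier
#'
#' @param X Numeric training matrix.
#' @param labels Logical vector, `TRUE` = active; both classes required.
#' @param config A [svm_config()].
#' @return A `bq_svm` model.
#' @export
fit_svm <- function(X, labels, config = svm_config()) {
  X <- as.matrix(X); labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("single-class training data for SVM", call. = FALSE)
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
  y <- factor(ifelse(labels, "active", "inactive"), levels = c("inactive", "active"))
  fit <- e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = config$cost,
                    scale = apply(X, 2, stats::sd) > 0)
  structure(list(fit = fit), class = "bq_svm")
}

#' @export
predict.bq_svm <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, as.matrix(newdata))) == "active"
}

#' Leave-one-out cross validation
#'
#' For each training row, the model is refit on the remaining rows and the
#' held-out row is predicted. A fold whose refit degenerates (e.g. a
#' classifier left with a single class) predicts the majority label of the
#' remaining rows; such folds are recorded in the `degenerate_folds`
#' attribute.
#'
#' @param fit_fun Function `(X, y) -> model`.
#' @param predict_fun Function `(model, X) -> predictions` (default
#'   `predict`).
#' @param X Numeric training matrix (>= 3 rows).
#' @param y Response vector (numeric, or logical for classification).
#' @return Vector of held-out predictions in row order.
#' @export
loo_cv <- function(fit_fun, X, y, predict_fun = stats::predict) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows for LOO-CV", call. = FALSE)
  out <- if (is.logical(y)) logical(n) else numeric(n)
  degenerate <- integer()
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    pred <- tryCatch({
      m <- fit_fun(Xi, yi)
      predict_fun(m, X[i, , drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(pred)) {
      degenerate <- c(degenerate, i)
      pred <- if (is.logical(y)) mean(yi) >= 0.5 else mean(yi)
    }
    out[i] <- pred[1]
  }
  attr(out, "degenerate_folds") <- degenerate
  out
}

# Squared Pearson correlation; 0 when undefined (constant predictions),
# consistent with reporting r2 = 0.000 alongside a nonzero RMSE.
r_squared <- function(obs, pred) {
  if (length(obs) < 2L || stats::sd(obs) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(obs, pred)^2
}

#' Evaluate a regression back-end over a train/test split
#'
#' @param X Full descriptor matrix (all compounds).
#' @param y Full response vector (log10 IC50); rows with missing response
#'   are excluded from both partitions.
#' @param split A `bq_split`.
#' @param fit_fun Function `(X, y) -> model`.
#' @return A `bq_regreport`: R2 (training self-fit squared correlation),
#'   Q2 and RMSE (leave-one-out on training), r2 (independent test squared
#'   correlation), plus partition sizes.
#' @export
evaluate_regression <- function(X, y, split, fit_fun) {
  X <- as.matrix(X)
  tr <- intersect(split$train, which(!is.na(y)))
  te <- intersect(split$test, which(!is.na(y)))
  if (!length(te)) stop("empty test set after removing missing activities",
                        call. = FALSE)
  model <- fit_fun(X[tr, , drop = FALSE], y[tr])
  pred_tr <- stats::predict(model, X[tr, , drop = FALSE])
  cv <- loo_cv(fit_fun, X[tr, , drop = FALSE], y[tr])
  pred_te <- stats::predict(model, X[te, , drop = FALSE])
  structure(list(R2 = r_squared(y[tr], pred_tr),
                 Q2 = r_squared(y[tr], as.numeric(cv)),
                 RMSE = sqrt(mean((y[tr] - as.numeric(cv))^2)),
                 r2 = r_squared(y[te], pred_te),
                 n_train = length(tr), n_test = length(te)),
            class = "bq_regreport")
}

#' Evaluate a classification back-end over a train/test split
#'
#' The three accuracies mirror the standard evaluation grid: At = training
#' self-fit, Av = leave-one-out cross-validated accuracy on training, Ap =
#' independent-test accuracy. Integer numerators and denominators are
#' retained so every reported value is reconstructable as n/D.
#'
#' @param X Full descriptor matrix.
#' @param labels Full logical label vector (NA rows excluded).
#' @param split A `bq_split`.
#' @param fit_fun Function `(X, labels) -> model`.
#' @return A `bq_classreport` with At/Av/Ap and their integer counts.
#' @export
evaluate_classification <- function(X, labels, split, fit_fun) {
  X <- as.matrix(X)
  tr <- intersect(split$train, which(!is.na(labels)))
  te <- intersect(split$test, which(!is.na(labels)))
  if (!length(te)) stop("empty test set after removing missing activities",
                        call. = FALSE)
  model <- fit_fun(X[tr, , drop = FALSE], labels[tr])
  cls <- function(p) if (is.logical(p)) p else p > 0.5
  pred_tr <- cls(stats::predict(model, X[tr, , drop = FALSE]))
  cv <- cls(as.vector(loo_cv(fit_fun, X[tr, , drop = FALSE], labels[tr])))
  pred_te <- cls(stats::predict(model, X[te, , drop = FALSE]))
  counts <- function(obs, pred) c(n = sum(obs == pred), d = length(obs))
  at <- counts(labels[tr], pred_tr)
  av <- counts(labels[tr], cv)
  ap <- counts(labels[te], pred_te)
  structure(list(At = at[["n"]] / at[["d"]], Av = av[["n"]] / av[["d"]],
                 Ap = ap[["n"]] / ap[["d"]],
                 counts = list(At = at, Av = av, Ap = ap)),
            class = "bq_classreport")
}

#' @export
print.bq_regreport <- function(x, ...) {
  cat(sprintf("R2 %.3f | Q2 %.3f | RMSE %.3f | r2 %.3f (train %d / test %d)\n",
              x$R2, x$Q2, x$RMSE, x$r2, x$n_train, x$n_test))
  invisible(x)
}

#' @export
print.bq_classreport <- function(x, ...) {
  cat(sprintf("At %.3f (%d/%d) | Av %.3f (%d/%d) | Ap %.3f (%d/%d)\n",
              x$At, x$counts$At[["n"]], x$counts$At[["d"]],
              x$Av, x$counts$Av[["n"]], x$counts$Av[["d"]],
              x$Ap, x$counts$Ap[["n"]], x$counts$Ap[["d"]]))
  invisible(x)
}
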