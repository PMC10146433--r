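#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares regression against coded class membership. Binary
#' coding uses a single response column with the literal codes 1 and 2;
#' multiclass coding uses one 0/1 indicator column per class. Predictors and
#' responses are mean-centered on the training set; latent variables are
#' extracted by the iterative NIPALS covariance-maximizing decomposition with
#' deflation (convergence tolerance 1e-12 on the score vector, at most 500
#' iterations per factor). The fit is fully deterministic, so identical input
#' reproduces the model bit for bit.
#'
#' @param train a [fingerprint_matrix] (or numeric matrix) of training
#'   predictors.
#' @param labels integer class labels, one per training row; at least two
#'   classes must be present. Binary coding requires labels in {1, 2}.
#' @param n_factors number of latent variables, between 1 and
#'   `min(n_train - 1, n_features)`.
#' @param coding `"binary"` or `"multiclass"`.
#' @return An object of class `plsda_model`: centering vectors `x_means` /
#'   `y_means`, per-factor `weights` (W), `x_loadings` (P), `y_loadings` (C),
#'   `scores` (T), `coding`, `classes`, `n_factors`, and the derived
#'   `regression_coefficients` (features x response columns).
#' @export
fit_plsda <- function(train, labels, n_factors, coding = c("binary", "multiclass")) {
  coding <- match.arg(coding)
  x <- if (inherits(train, "fingerprint_matrix")) train$values else as.matrix(train)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    hs_stop_invalid("one label per training row is required")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    hs_stop_invalid("training set must contain at least two classes")
  if (coding == "binary" && !all(classes %in% 1:2))
    hs_stop_invalid("binary coding requires labels in {1, 2}")
  n <- nrow(x); p <- ncol(x)
  if (!is_count(n_factors) || n_factors > min(n - 1L, p))
    hs_stop_invalid(sprintf("n_factors must be in [1, %d]", min(n - 1L, p)))

  y <- code_labels(labels, coding, classes)
  x_means <- colMeans(x)
  y_means <- colMeans(y)
  xc <- sweep(x, 2L, x_means)
  yc <- sweep(y, 2L, y_means)

  dec <- nipals_pls(xc, yc, n_factors)

  b <- pls_coefficients(dec$weights, dec$x_loadings, dec$y_loadings, n_factors)
  structure(list(x_means = x_means, y_means = y_means,
                 weights = dec$weights, x_loadings = dec$x_loadings,
                 y_loadings = dec$y_loadings, scores = dec$scores,
                 n_factors = as.integer(n_factors),
                 coding = coding, classes = classes,
                 regression_coefficients = b),
            class = "plsda_model")
}

# 1/2 codes (single column) or one-hot indicators
code_labels <- function(labels, coding, classes) {
  if (coding == "binary") matrix(as.numeric(labels), ncol = 1L)
  else vapply(classes, function(k) as.numeric(labels == k),
              numeric(length(labels)))
}

# NIPALS with deflation of X and Y; xc/yc already centered
nipals_pls <- function(xc, yc, a_max, tol = 1e-12, max_iter = 500L) {
  n <- nrow(xc); p <- ncol(xc); q <- ncol(yc)
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  C <- matrix(0, q, a_max); Tm <- matrix(0, n, a_max)
  for (a in seq_len(a_max)) {
    u <- yc[, which.max(apply(yc, 2L, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps)
        hs_stop_invalid(sprintf("predictors exhausted after %d factors; n_factors too large", a - 1L))
      w <- w / nw
      t <- as.vector(xc %*% w)
      cc <- crossprod(yc, t) / sum(t^2)
      if (q == 1L) break
      u_new <- as.vector(yc %*% cc) / sum(cc^2)
      if (sqrt(sum((t - t_old)^2)) < tol * max(1, sqrt(sum(t^2)))) { u <- u_new; break }
      t_old <- t; u <- u_new
    }
    tt <- sum(t^2)
    if (tt < .Machine$double.eps)
      hs_stop_invalid(sprintf("predictors exhausted after %d factors; n_factors too large", a - 1L))
    pvec <- crossprod(xc, t) / tt
    W[, a] <- w; P[, a] <- pvec; C[, a] <- cc; Tm[, a] <- t
    xc <- xc - tcrossprod(t, pvec)
    yc <- yc - tcrossprod(t, cc)
  }
  list(weights = W, x_loadings = P, y_loadings = C, scores = Tm)
}

# B_k = W_k (P_k' W_k)^{-1} C_k'
pls_coefficients <- function(W, P, C, k) {
  Wk <- W[, seq_len(k), drop = FALSE]
  Pk <- P[, seq_len(k), drop = FALSE]
  Ck <- C[, seq_len(k), drop = FALSE]
  R <- Wk %*% solve(crossprod(Pk, Wk))
  R %*% t(Ck)
}

#' Predicted response codes from a PLS-DA model
#'
#' @param model a [fit_plsda()] model.
#' @param samples a [fingerprint_matrix] or numeric matrix with the model's
#'   feature count.
#' @param n_factors number of latent variables to use (default: the model's).
#' @return Numeric matrix of predicted codes (samples x response columns).
#' @export
predict_codes <- function(model, samples, n_factors = model$n_factors) {
  stopifnot(inherits(model, "plsda_model"))
  x <- if (inherits(samples, "fingerprint_matrix")) samples$values else as.matrix(samples)
  if (ncol(x) != length(model$x_means))
    hs_stop_invalid("feature count does not match the model")
  if (!is_count(n_factors) || n_factors > ncol(model$weights))
    hs_stop_invalid("n_factors exceeds the fitted decomposition")
  b <- if (n_factors == model$n_factors) model$regression_coefficients
       else pls_coefficients(model$weights, model$x_loadings, model$y_loadings, n_factors)
  sweep(sweep(x, 2L, model$x_means) %*% b, 2L, model$y_means, "+")
}

#' Classify samples with a PLS-DA model
#'
#' Binary coding: predicted class is 1 when the predicted code falls below
#' 1.5 (the midpoint of the 1/2 codes), otherwise 2. Multiclass coding:
#' argmax over the class indicator predictions, ties toward the lowest class
#' index.
#'
#' @inheritParams predict_codes
#' @return Integer vector of predicted class labels.
#' @export
predict_classes <- function(model, samples, n_factors = model$n_factors) {
  yhat <- predict_codes(model, samples, n_factors)
  decide_classes(yhat, model$coding, model$classes)
}

# decision rule on predicted codes; exposed for direct testing via predict_classes
decide_classes <- function(yhat, coding, classes) {
  if (coding == "binary") ifelse(yhat[, 1L] < 1.5, 1L, 2L)
  else classes[apply(yhat, 1L, which.max)]      # which.max: lowest index on ties
}

#' Select the number of PLS factors by stratified k-fold cross-validation
#'
#' Builds `folds` label-stratified, disjoint folds from a fixed seed
#' (class-wise shuffling dealt round-robin), fits the model on each training
#' complement once with `max_factors` latent variables, predicts the held-out
#' fold at every factor count, and pools all held-out predictions into one
#' correct-classification-rate (ccr%) per factor count. The chosen factor
#' count maximizes the pooled ccr; ties go to the fewest factors.
#'
#' @param train a [fingerprint_matrix] or numeric matrix.
#' @param labels integer class labels per row.
#' @param coding `"binary"` or `"multiclass"`.
#' @param folds number of cross-validation folds (default 10).
#' @param max_factors largest factor count examined (default 30).
#' @param seed integer seed for the fold assignment.
#' @return A list: `n_factors` (chosen), `ccr` (ccr% for factor counts
#'   `1:max_factors`), `fold_assignment` (integer fold id per row).
#' @export
cross_validate_lv <- function(train, labels, coding = c("binary", "multiclass"),
                              folds = 10L, max_factors = 30L, seed = 1L) {
  coding <- match.arg(coding)
  x <- if (inherits(train, "fingerprint_matrix")) train$values else as.matrix(train)
  labels <- as.integer(labels)
  n <- nrow(x)
  if (!is_count(folds) || folds < 2L || n < folds)
    hs_stop_invalid("need 2 <= folds <= n")

  fold_of <- stratified_folds(labels, folds, seed)
  classes <- sort(unique(labels))
  for (f in seq_len(folds)) {
    tr_lab <- labels[fold_of != f]
    if (!all(classes %in% tr_lab))
      hs_stop(sprintf("fold %d removes every member of a class from the training set", f),
              "stratification_failure")
    if (max_factors > min(sum(fold_of != f) - 1L, ncol(x)))
      hs_stop_invalid(sprintf("max_factors (%d) is inadmissible in fold %d", max_factors, f))
  }

  pred <- matrix(NA_integer_, n, max_factors)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    model <- fit_plsda(x[tr, , drop = FALSE], labels[tr], max_factors, coding)
    for (k in seq_len(max_factors))
      pred[!tr, k] <- predict_classes(model, x[!tr, , drop = FALSE], k)
  }
  ccr <- 100 * colMeans(pred == labels)
  list(n_factors = which.max(ccr), ccr = ccr, fold_assignment = fold_of)
}

# label-stratified fold ids: shuffle within class, deal round-robin with a
# running counter so fold sizes stay balanced across classes
stratified_folds <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  fold_of <- integer(length(labels))
  counter <- 0L
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- ((counter + seq_along(idx) - 1L) %% folds) + 1L
    counter <- counter + length(idx)
  }
  fold_of
}

#' Classification report
#'
#' Confusion matrix and correct classification rate. The ccr is kept at full
#' precision in `ccr` and rounded to the nearest integer percent in
#' `ccr_display`.
#'
#' @param true_labels,predicted_labels equal-length integer label vectors.
#' @param sample_ids optional identifiers used to report misclassified
#'   samples.
#' @param classes optional vector of admissible labels; labels outside it
#'   raise an error.
#' @return An object of class `classification_report`: `confusion` (true x
#'   predicted counts), `ccr`, `ccr_display`, `misclassified_ids`.
#' @export
evaluate <- function(true_labels, predicted_labels, sample_ids = NULL,
                     classes = NULL) {
  if (length(true_labels) != length(predicted_labels))
    hs_stop_invalid("label vectors must have equal length")
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  lev <- if (is.null(classes)) sort(unique(c(true_labels, predicted_labels)))
         else sort(unique(as.integer(classes)))
  if (!all(c(true_labels, predicted_labels) %in% lev))
    hs_stop_invalid("labels fall outside the declared coding")
  conf <- table(true = factor(true_labels, levels = lev),
                predicted = factor(predicted_labels, levels = lev))
  n <- length(true_labels)
  ccr <- 100 * sum(diag(conf)) / n
  wrong <- which(true_labels != predicted_labels)
  ids <- if (is.null(sample_ids)) as.character(wrong) else sample_ids[wrong]
  structure(list(confusion = conf, ccr = ccr,
                 ccr_display = round(ccr), misclassified_ids = ids),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> ccr %d%% (%.4f%%), %d misclassified\n",
              x$ccr_display, x$ccr, length(x$misclassified_ids)))
  print(x$confusion)
  invisible(x)
}
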