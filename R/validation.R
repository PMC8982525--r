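#' Cross-validated q2
#'
#' Pooled predictive q2 = 1 - PRESS / SS_tot, with SS_tot taken about the
#' full-sample mean. `LOO` refits n times leaving one compound out; `L20`
#' uses 5 disjoint folds built by rank-striping on the response (rank 1,
#' 6, 11, ... in fold 1 and so on), which stratifies every fold across
#' the activity range and is fully deterministic.
#'
#' @param X descriptor matrix (training compounds only).
#' @param y response vector.
#' @param spec a [regressor_spec()].
#' @param scheme "LOO" or "L20".
#' @export
cv_r2 <- function(X, y, spec = regressor_spec(), scheme = c("LOO", "L20")) {
  scheme <- match.arg(scheme)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 5L)
  folds <- if (scheme == "LOO") as.list(seq_len(n)) else {
    ord <- order(-y, seq_len(n))       # most active first, ties by index
    f <- lapply(1:5, function(k) ord[seq(k, n, by = 5L)])
    f
  }
  pred <- rep(NA_real_, n)
  for (hold in folds) {
    fit <- fit_regressor(X[-hold, , drop = FALSE], y[-hold], spec)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  1 - sum((pred - y)^2) / sum((y - mean(y))^2)
}

#' Predictive r2 from PRESS on an external test set
#'
#' \deqn{r^2_{PRESS} = (SD - PRESS)/SD} with
#' SD = sum((y_test - train_mean)^2) and
#' PRESS = sum((y_test - y_pred)^2). Equals 1 for exact predictions, 0
#' for a model no better than predicting the training mean, and is
#' negative below that baseline.
#'
#' @param y_test observed test activities.
#' @param y_pred predicted test activities.
#' @param train_mean mean activity of the training set.
#' @export
r_press <- function(y_test, y_pred, train_mean) {
  stopifnot(length(y_test) == length(y_pred), length(y_test) >= 1L)
  SD <- sum((y_test - train_mean)^2)
  if (SD <= 0) stop("SD is zero: test activities all equal the training mean")
  PRESS <- sum((y_test - y_pred)^2)
  (SD - PRESS) / SD
}

#' Full validation report for a descriptor subset
#'
#' Fits the regressor on the training rows of the selected columns and
#' reports resubstitution r2, LOO and L20 q2 (training compounds) and
#' predictive r2 from PRESS on the test compounds.
#'
#' @param matrix a `DescriptorMatrix`.
#' @param split list with `train`/`test` id vectors from
#'   [split_train_test()].
#' @param subset character vector of descriptor column names.
#' @param spec a [regressor_spec()].
#' @return A `ValidationReport` list: `r2_resub`, `r2_loo`, `r2_l20`,
#'   `r2_press`, `SD`, `PRESS`, `selected_descriptors`, `model`.
#' @export
validate_model <- function(matrix, split, subset, spec = regressor_spec()) {
  if (!length(subset)) stop("empty descriptor subset")
  missing <- setdiff(subset, colnames(matrix$values))
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  tr <- match(split$train, matrix$ids)
  te <- match(split$test, matrix$ids)
  Xtr <- matrix$values[tr, subset, drop = FALSE]
  ytr <- matrix$activity[tr]
  Xte <- matrix$values[te, subset, drop = FALSE]
  yte <- matrix$activity[te]
  fit <- fit_regressor(Xtr, ytr, spec)
  resub <- stats::cor(predict(fit, Xtr), ytr)^2
  loo <- cv_r2(Xtr, ytr, spec, "LOO")
  l20 <- cv_r2(Xtr, ytr, spec, "L20")
  pred_te <- predict(fit, Xte)
  SD <- sum((yte - mean(ytr))^2)
  PRESS <- sum((yte - pred_te)^2)
  structure(list(r2_resub = resub, r2_loo = loo, r2_l20 = l20,
                 r2_press = r_press(yte, pred_te, mean(ytr)),
                 SD = SD, PRESS = PRESS,
                 selected_descriptors = subset, model = fit),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat(sprintf(
    "<ValidationReport: r2 %.3f | q2_L20 %.3f | q2_LOO %.3f | r2_PRESS %.3f (%d descriptors)>\n",
    x$r2_resub, x$r2_l20, x$r2_loo, x$r2_press,
    length(x$selected_descriptors)))
  invisible(x)
}
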