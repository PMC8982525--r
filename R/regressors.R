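#' Regressor specifications and fitting
#'
#' Pluggable regression learners behind one `fit_regressor()` /
#' `predict()` contract, covering the methods a GA feature-selection
#' wrapper typically drives: multiple linear regression (MLR),
#' nu-support-vector regression with an RBF kernel (solved as a dense
#' quadratic program — adequate for the n < 100 training sets these
#' models use), and a small bagged-tree random forest. Additional
#' learners can be injected through the `plugin` hook (a list with `fit`
#' and `predict` functions).
#'
#' @param method "MLR", "SVR", "RF" or "plugin".
#' @param nu nu-SVR parameter: upper bound on the fraction of margin
#'   errors, lower bound on the support-vector fraction (default 0.664).
#' @param gamma RBF kernel coefficient; 0 means the auto convention
#'   1/n_features (a literal zero would flatten the kernel).
#' @param cost SVR box constraint C (default 1, the LibSVM default).
#' @param epsilon_termination recorded solver tolerance (default 0.001).
#' @param cache recorded kernel cache size in MB; inert here.
#' @param loss recorded epsilon-loss width; inert under nu-SVR (it
#'   applies to epsilon-SVR only) but kept so configurations round-trip.
#' @param n_trees,min_node random-forest size knobs.
#' @param seed integer seed for stochastic learners.
#' @param plugin list(fit = function(X, y, seed), predict =
#'   function(model, X)).
#' @return A `RegressorSpec` list.
#' @export
regressor_spec <- function(method = c("MLR", "SVR", "RF", "plugin"),
                           nu = 0.664, gamma = 0, cost = 1,
                           epsilon_termination = 0.001, cache = 40,
                           loss = 0.1, n_trees = 100L, min_node = 5L,
                           seed = 1L, plugin = NULL) {
  method <- match.arg(method)
  stopifnot(nu > 0, nu <= 1)
  if (method == "plugin" && (is.null(plugin$fit) || is.null(plugin$predict)))
    stop("plugin method needs fit and predict functions")
  structure(list(method = method, nu = nu, gamma = gamma, cost = cost,
                 epsilon_termination = epsilon_termination, cache = cache,
                 loss = loss, n_trees = as.integer(n_trees),
                 min_node = as.integer(min_node), seed = as.integer(seed),
                 plugin = plugin),
            class = "RegressorSpec")
}

#' Fit a regressor to a descriptor block
#'
#' @param X numeric matrix (rows = compounds).
#' @param y numeric response (log(1/IC50)).
#' @param spec a [regressor_spec()].
#' @return A `PredictiveModel` supporting [predict()].
#' @export
fit_regressor <- function(X, y, spec = regressor_spec()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  fitted <- switch(spec$method,
    MLR = .fit_mlr(X, y),
    SVR = .fit_nusvr(X, y, spec),
    RF = .fit_rf(X, y, spec),
    plugin = list(kind = "plugin", obj = spec$plugin$fit(X, y, spec$seed),
                  predict_fn = spec$plugin$predict))
  structure(c(fitted, list(columns = colnames(X))), class = "PredictiveModel")
}

#' @param object a `PredictiveModel`.
#' @param newdata matrix with the model's descriptor columns.
#' @param ... unused.
#' @rdname fit_regressor
#' @export
predict.PredictiveModel <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(X)) &&
      all(object$columns %in% colnames(X)))
    X <- X[, object$columns, drop = FALSE]
  switch(object$kind,
    mlr = as.numeric(cbind(1, X) %*% object$coef),
    svr = .predict_nusvr(object, X),
    rf = .predict_rf(object, X),
    plugin = object$predict_fn(object$obj, X))
}

## ---- MLR -------------------------------------------------------------

.fit_mlr <- function(X, y) {
  if (nrow(X) < ncol(X) + 1L)
    stop("MLR needs more rows than descriptors; use fewer descriptors")
  fit <- stats::lm.fit(cbind(1, X), y)
  if (any(is.na(fit$coefficients)))
    stop("singular MLR design; use fewer (less collinear) descriptors")
  list(kind = "mlr", coef = fit$coefficients)
}

#' Evaluate a printed linear QSAR equation
#'
#' Computes intercept + sum(coefficient * descriptor) for named
#' coefficients, erroring on any descriptor missing from the input.
#'
#' @param coefficients named numeric vector of slopes.
#' @param intercept numeric intercept.
#' @param descriptors named numeric vector (or 1-row data.frame) of
#'   descriptor values.
#' @export
mlr_equation_eval <- function(coefficients, intercept, descriptors) {
  descriptors <- unlist(descriptors)
  missing <- setdiff(names(coefficients), names(descriptors))
  if (length(missing))
    stop("missing descriptor value(s): ", paste(missing, collapse = ", "))
  intercept + sum(coefficients * descriptors[names(coefficients)])
}

## ---- nu-SVR (RBF kernel) via quadratic programming -------------------
#
# LibSVM-style nu-SVR dual in beta = (alpha, alpha*):
#   min 1/2 (a - a*)' K (a - a*) - y'(a - a*)
#   s.t. sum(a - a*) = 0, sum(a + a*) = C * nu,
#        0 <= a_i, a*_i <= C / n
# Inputs are z-scored on the training data (scaling stored with the
# model). A tiny ridge keeps the 2n x 2n Hessian positive definite for
# the solver.

.rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

.fit_nusvr <- function(X, y, spec) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  gamma <- if (spec$gamma <= 0) 1 / ncol(X) else spec$gamma
  K <- .rbf_kernel(Z, Z, gamma)
  C <- spec$cost; ub <- C / n
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  d <- c(y, -y)
  # equality: sum(a - a*) = 0 ; sum(a + a*) = C * nu  (meq = 2)
  Aeq <- rbind(c(rep(1, n), rep(-1, n)), rep(1, 2 * n))
  Aineq <- rbind(diag(2 * n), -diag(2 * n))
  Amat <- t(rbind(Aeq, Aineq))
  bvec <- c(0, C * spec$nu, rep(0, 2 * n), rep(-ub, 2 * n))
  sol <- quadprog::solve.QP(H, d, Amat, bvec, meq = 2)
  a <- sol$solution[seq_len(n)]; as <- sol$solution[n + seq_len(n)]
  theta <- a - as
  f0 <- as.numeric(K %*% theta)
  tol <- ub * 1e-6
  free_a <- which(a > tol & a < ub - tol)
  free_as <- which(as > tol & as < ub - tol)
  # for free alpha: y - f0 = b + eps ; for free alpha*: y - f0 = b - eps
  if (length(free_a) && length(free_as)) {
    ra <- mean(y[free_a] - f0[free_a]); rs <- mean(y[free_as] - f0[free_as])
    b <- (ra + rs) / 2
  } else if (length(free_a)) b <- mean(y[free_a] - f0[free_a])
  else if (length(free_as)) b <- mean(y[free_as] - f0[free_as])
  else b <- mean(y - f0)
  list(kind = "svr", theta = theta, b = b, gamma = gamma,
       Ztrain = Z, mu = mu, sdv = sdv)
}

.predict_nusvr <- function(model, X) {
  Z <- sweep(sweep(as.matrix(X), 2, model$mu), 2, model$sdv, "/")
  as.numeric(.rbf_kernel(Z, model$Ztrain, model$gamma) %*% model$theta +
             model$b)
}

## ---- random forest (bagged variance-reduction trees) -----------------

.fit_rf <- function(X, y, spec) {
  n <- nrow(X); p <- ncol(X)
  mtry <- max(1L, floor(p / 3))
  # keep the caller's RNG stream untouched
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  trees <- vector("list", spec$n_trees)
  for (t in seq_len(spec$n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- .grow_tree(X[idx, , drop = FALSE], y[idx], mtry,
                             spec$min_node)
  }
  list(kind = "rf", trees = trees)
}

.grow_tree <- function(X, y, mtry, min_node) {
  if (length(y) < 2L * min_node || stats::var(y) < 1e-12)
    return(list(leaf = TRUE, value = mean(y)))
  vars <- sample.int(ncol(X), min(mtry, ncol(X)))
  best <- NULL; best_score <- Inf
  for (v in vars) {
    xs <- X[, v]
    cuts <- unique(stats::quantile(xs, probs = seq(0.1, 0.9, by = 0.1),
                                   names = FALSE, type = 1))
    for (cut in cuts) {
      left <- xs <= cut
      nl <- sum(left); nr <- length(y) - nl
      if (nl < min_node || nr < min_node) next
      score <- nl * stats::var(y[left]) + nr * stats::var(y[!left])
      if (score < best_score) { best_score <- score; best <- list(v, cut) }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(y)))
  left <- X[, best[[1]]] <= best[[2]]
  list(leaf = FALSE, var = best[[1]], cut = best[[2]],
       left = .grow_tree(X[left, , drop = FALSE], y[left], mtry, min_node),
       right = .grow_tree(X[!left, , drop = FALSE], y[!left], mtry, min_node))
}

.predict_tree <- function(tree, x) {
  while (!tree$leaf)
    tree <- if (x[tree$var] <= tree$cut) tree$left else tree$right
  tree$value
}

.predict_rf <- function(model, X) {
  vapply(seq_len(nrow(X)), function(i) {
    mean(vapply(model$trees, .predict_tree, numeric(1), X[i, ]))
  }, numeric(1))
}
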