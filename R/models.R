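# Blood-pressure regressors: Lasso, support vector regression, Gaussian
# process regression, and the flat (no-change) control model.

#' Model specification
#'
#' @param kind one of "lasso", "svr", "gpr", "flat".
#' @param target "sbp" or "dbp" (bookkeeping; the fit uses the y it is given).
#' @param hyper named list of hyperparameters. lasso: `lambda` (fixed weight;
#'   otherwise chosen by CV). svr: `gamma` (kernel scale), `cost` (box
#'   constraint), `epsilon` (insensitive-band width); otherwise tuned by a
#'   seeded randomized search (`n_iter`, default 30) with subject-stratified
#'   CV on at most `tune_subsample` rows, final fit on at most
#'   `fit_subsample` rows. gpr: `lengthscale`, `sigma_f`, `noise`; otherwise
#'   optimized by L-BFGS-B on the log marginal likelihood (fit capped at
#'   `fit_subsample` rows, default 800). flat: `cal_col` names the
#'   calibration-reference column to echo; without it the model predicts the
#'   training-set mean.
#' @param seed integer seed for all randomness of the fit.
#' @return list of class `bp_model_spec`.
#' @export
bp_model_spec <- function(kind = c("lasso", "svr", "gpr", "flat"),
                          target = c("sbp", "dbp"), hyper = list(), seed = 1) {
  kind <- match.arg(kind)
  target <- match.arg(target)
  structure(list(kind = kind, target = target, hyper = hyper, seed = seed),
            class = "bp_model_spec")
}

as_feature_matrix <- function(X, feature_names = NULL) {
  Xm <- as.matrix(as.data.frame(X, check.names = FALSE)[,
    feature_names %||% colnames(X), drop = FALSE])
  storage.mode(Xm) <- "double"
  Xm
}

check_features <- function(newdata, feature_names) {
  miss <- setdiff(feature_names, colnames(newdata))
  if (length(miss))
    stop("predict: missing feature(s): ", paste(miss, collapse = ", "))
}

# ---- Gaussian process regression (squared-exponential kernel) ----

sq_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

gp_nlml <- function(theta, X, y) {
  l <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
  n <- length(y)
  K <- sf^2 * exp(-sq_dist(X, X) / (2 * l^2)) + (sn^2 + 1e-10) * diag(n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

gp_fit <- function(X, y, lengthscale = NULL, sigma_f = NULL, noise = NULL) {
  ym <- mean(y); yc <- y - ym
  d2 <- sq_dist(X, X)
  med <- sqrt(median(d2[upper.tri(d2)]))
  if (med == 0 || !is.finite(med)) med <- 1
  l0 <- lengthscale %||% med
  sf0 <- sigma_f %||% max(sd(yc), 1e-3)
  sn0 <- noise %||% max(0.1 * sd(yc), 1e-4)
  theta <- log(c(l0, sf0, sn0))
  if (is.null(lengthscale) || is.null(sigma_f) || is.null(noise)) {
    opt <- optim(theta, gp_nlml, X = X, y = yc, method = "L-BFGS-B",
                 lower = theta - 6, upper = theta + 6,
                 control = list(maxit = 60))
    theta <- opt$par
    # honor any fixed hyperparameter
    if (!is.null(lengthscale)) theta[1] <- log(lengthscale)
    if (!is.null(sigma_f)) theta[2] <- log(sigma_f)
    if (!is.null(noise)) theta[3] <- log(noise)
  }
  l <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
  K <- sf^2 * exp(-d2 / (2 * l^2)) + (sn^2 + 1e-10) * diag(length(y))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(X = X, alpha = alpha, y_mean = ym,
       lengthscale = l, sigma_f = sf, noise = sn)
}

gp_predict <- function(fit, Xnew) {
  Ks <- fit$sigma_f^2 * exp(-sq_dist(Xnew, fit$X) / (2 * fit$lengthscale^2))
  as.numeric(Ks %*% fit$alpha) + fit$y_mean
}

# ---- SVR randomized hyperparameter search ----

svr_tune <- function(X, y, groups, n_iter, k, seed) {
  p <- ncol(X)
  draws <- withr::with_seed(seed, data.frame(
    gamma = 10^runif(n_iter, -3, 0.5) / p,
    cost = 10^runif(n_iter, -1, 2.5),
    epsilon = 10^runif(n_iter, -2, 0)
  ))
  foldid <- subject_folds(groups, k = k, seed = seed)
  k_eff <- max(foldid)
  cv_mse <- vapply(seq_len(n_iter), function(i) {
    errs <- numeric(0)
    for (f in seq_len(k_eff)) {
      tr <- foldid != f
      if (!any(tr) || all(tr)) next
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", gamma = draws$gamma[i],
                      cost = draws$cost[i], epsilon = draws$epsilon[i],
                      scale = FALSE)
      errs <- c(errs, (predict(m, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }
    mean(errs)
  }, numeric(1))
  as.list(draws[which.min(cv_mse), ])
}

#' Fit a blood-pressure regressor
#'
#' Trains the model named by the spec on the (already feature-selected)
#' training table, with subject-stratified cross-validation for
#' hyperparameters. Features are standardized with training statistics that
#' are stored and reused at prediction time.
#'
#' @param spec a [bp_model_spec()].
#' @param X training features (data.frame or matrix with column names).
#' @param y training target, mmHg.
#' @param groups subject ids (required for CV-tuned kinds).
#' @param k CV folds.
#' @return object of class `bp_model`.
#' @export
fit_bp_model <- function(spec, X, y, groups = NULL, k = 10) {
  stopifnot(inherits(spec, "bp_model_spec"))
  h <- spec$hyper
  if (spec$kind == "flat") {
    return(structure(list(spec = spec, mean_bp = mean(y),
                          cal_col = h$cal_col %||% NULL,
                          feature_names = if (is.null(h$cal_col)) character(0) else h$cal_col),
                     class = "bp_model"))
  }
  Xm <- as_feature_matrix(X)
  if (is.null(groups)) groups <- seq_along(y)
  const <- apply(Xm, 2, sd) == 0
  if (any(const)) Xm <- Xm[, !const, drop = FALSE]
  sc <- standardize_fit(Xm)
  Xs <- standardize_apply(Xm, sc)
  fitted <- switch(spec$kind,
    lasso = {
      sel <- lasso_select(Xs, y, groups, k = k, seed = spec$seed)
      if (!is.null(h$lambda)) {
        cf <- coef(sel$fit, s = h$lambda, exact = TRUE, x = Xs, y = y)
        list(beta = setNames(as.numeric(cf[-1]), rownames(cf)[-1]),
             intercept = as.numeric(cf[1]), lambda = h$lambda)
      } else {
        list(beta = sel$coefficients, intercept = sel$intercept,
             lambda = sel$lambda)
      }
    },
    svr = {
      n <- nrow(Xs)
      tune_n <- min(h$tune_subsample %||% 1000L, n)
      idx_t <- withr::with_seed(derive_seed(spec$seed, 2L), sample.int(n, tune_n))
      pars <- if (!is.null(h$gamma) && !is.null(h$cost) && !is.null(h$epsilon)) {
        h[c("gamma", "cost", "epsilon")]
      } else {
        svr_tune(Xs[idx_t, , drop = FALSE], y[idx_t], groups[idx_t],
                 n_iter = h$n_iter %||% 30L, k = k, seed = spec$seed)
      }
      fit_n <- min(h$fit_subsample %||% 3000L, n)
      idx_f <- withr::with_seed(derive_seed(spec$seed, 3L), sample.int(n, fit_n))
      m <- e1071::svm(Xs[idx_f, , drop = FALSE], y[idx_f],
                      type = "eps-regression", kernel = "radial",
                      gamma = pars$gamma, cost = pars$cost,
                      epsilon = pars$epsilon, scale = FALSE)
      list(svm = m, pars = pars)
    },
    gpr = {
      n <- nrow(Xs)
      fit_n <- min(h$fit_subsample %||% 800L, n)
      idx_f <- withr::with_seed(derive_seed(spec$seed, 4L), sample.int(n, fit_n))
      gp_fit(Xs[idx_f, , drop = FALSE], y[idx_f],
             lengthscale = h$lengthscale, sigma_f = h$sigma_f,
             noise = h$noise)
    }
  )
  structure(list(spec = spec, fitted = fitted,
                 feature_names = colnames(Xm), scaling = sc),
            class = "bp_model")
}

#' Predict blood pressure
#'
#' @param object a `bp_model`.
#' @param newdata data.frame or matrix containing (at least) the features the
#'   model was trained on; a missing feature is an error naming it.
#' @param ... unused.
#' @return numeric vector of estimates in mmHg.
#' @export
predict.bp_model <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata, check.names = FALSE)
  if (object$spec$kind == "flat") {
    if (!is.null(object$cal_col)) {
      check_features(nd, object$cal_col)
      return(as.numeric(nd[[object$cal_col]]))
    }
    return(rep(object$mean_bp, nrow(nd)))
  }
  check_features(nd, object$feature_names)
  Xm <- as_feature_matrix(nd, object$feature_names)
  if (!all(is.finite(Xm))) stop("predict: non-finite feature values")
  Xs <- standardize_apply(Xm, object$scaling)
  out <- switch(object$spec$kind,
    lasso = as.numeric(Xs %*% object$fitted$beta) + object$fitted$intercept,
    svr = as.numeric(predict(object$fitted$svm, Xs)),
    gpr = gp_predict(object$fitted, Xs)
  )
  if (!all(is.finite(out))) stop("predict: non-finite prediction")
  out
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> kind = %s, target = %s, %d feature(s)\n",
              x$spec$kind, x$spec$target, length(x$feature_names)))
  invisible(x)
}
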