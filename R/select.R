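# Lasso feature selection and permutation feature relevance.

# Standardize a matrix with stored (or given) centers/scales; constant
# columns keep scale 1 so they map to 0.
standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}
standardize_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Lasso feature selection with subject-stratified cross-validation
#'
#' Features are standardized (training statistics only), constant columns
#' dropped with a warning, and the regularization weight chosen to minimize
#' the mean-squared error over a subject-stratified 10-fold cross-validation
#' on a 100-point log-spaced grid from lambda_max (the smallest weight
#' zeroing all coefficients, max |X'y~|/n on standardized data) down to
#' lambda_max * 1e-4. The model is refit on the full training set at the
#' chosen weight; selected features are the nonzero coefficients.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y target in mmHg.
#' @param groups subject id per row (folds never split a subject).
#' @param k number of CV folds.
#' @param nlambda grid size.
#' @param lambda_min_ratio grid lower end as a fraction of lambda_max.
#' @param seed seed for the fold assignment.
#' @return list of class `selection_result`: selected_features (ordered by
#'   decreasing |coefficient|), lambda, coefficients, n_selected, intercept,
#'   scaling, the glmnet fit and the CV object.
#' @export
lasso_select <- function(X, y, groups, k = 10, nlambda = 100,
                         lambda_min_ratio = 1e-4, seed = 1) {
  X <- as.matrix(X)
  const <- apply(X, 2, function(v) sd(v) == 0 || !is.finite(sd(v)))
  if (any(const)) {
    warning("lasso_select: dropping constant feature column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  sc <- standardize_fit(X)
  Xs <- standardize_apply(X, sc)
  n <- nrow(Xs)
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  foldid <- subject_folds(groups, k = k, seed = seed)
  if (max(foldid) <= 3L) {
    warning("lasso_select: fewer than 4 subjects; CV folds assigned per sample")
    foldid <- withr::with_seed(seed, sample(rep_len(seq_len(min(k, n)), n)))
  }
  # glmnet requires >= 2 columns; an all-zero dummy keeps a single-feature
  # problem well-posed without affecting the solution
  Xg <- if (ncol(Xs) == 1L) cbind(Xs, ".dummy" = 0) else Xs
  cv <- glmnet::cv.glmnet(Xg, y, lambda = grid, foldid = foldid,
                          standardize = FALSE)
  fit <- glmnet::glmnet(Xg, y, lambda = grid, standardize = FALSE)
  cf <- coef(fit, s = cv$lambda.min)
  beta <- setNames(as.numeric(cf[-1]), rownames(cf)[-1])
  beta <- beta[names(beta) != ".dummy"]
  nz <- beta[beta != 0]
  structure(list(
    selected_features = names(nz)[order(-abs(nz))],
    lambda = cv$lambda.min,
    coefficients = beta,
    intercept = as.numeric(cf[1]),
    n_selected = length(nz),
    scaling = sc,
    fit = fit,
    cv = cv,
    lambda_max = lambda_max
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> lambda = %.4g, %d of %d features selected\n",
              x$lambda, x$n_selected, length(x$coefficients)))
  invisible(x)
}

#' Permutation feature relevance
#'
#' For each feature, its values across all samples of the test set are
#' randomly permuted, the model re-predicts, and the relevance of one
#' repetition is the relative increase in the standard deviation of the
#' error: (STDE_permuted - STDE_original) / STDE_original. The procedure is
#' repeated `n_rep` times per feature (seeded, bit-reproducible): the RNG is
#' seeded once with `seed` and permutations are drawn sequentially, iterating
#' features in column order with repetitions innermost.
#'
#' @param model a fitted model accepted by [predict()] on a matrix/data.frame
#'   (e.g. a `bp_model`).
#' @param X_test test feature matrix/data.frame (subject-disjoint from
#'   training).
#' @param y_test test targets, mmHg.
#' @param n_rep permutation repetitions per feature.
#' @param seed integer seed.
#' @param features columns to score (default: all).
#' @return data.frame of class `relevance_report`: feature, mean_relevance,
#'   sd_relevance, n_permutations; rows in column order (rank with
#'   [rank_report()]).
#' @export
permutation_relevance <- function(model, X_test, y_test, n_rep = 100,
                                  seed = 1, features = colnames(X_test)) {
  Xm <- as.matrix(X_test)
  pred0 <- as.numeric(predict(model, X_test))
  stde0 <- sd(pred0 - y_test)
  if (stde0 == 0) stop("permutation_relevance: zero original STDE (degenerate fit)")
  n <- nrow(Xm)
  rel <- matrix(NA_real_, length(features), n_rep,
                dimnames = list(features, NULL))
  withr::with_seed(seed, {
    for (f in features) {
      Xp <- X_test
      for (r in seq_len(n_rep)) {
        perm <- sample.int(n)
        Xp[, f] <- Xm[perm, f]
        stde_p <- sd(as.numeric(predict(model, Xp)) - y_test)
        rel[f, r] <- (stde_p - stde0) / stde0
      }
    }
  })
  structure(data.frame(feature = features,
                       mean_relevance = rowMeans(rel),
                       sd_relevance = apply(rel, 1, sd),
                       n_permutations = n_rep,
                       row.names = NULL),
            class = c("relevance_report", "data.frame"))
}

#' Rank a relevance report
#'
#' Features in decreasing mean relevance, ties broken by feature name
#' (lexicographic). Calibration-segment features keep their `cal.` prefix.
#'
#' @param rel a `relevance_report`.
#' @param top_k keep the first k rows (default all).
#' @return the ranked data.frame with a `rank` column.
#' @export
rank_report <- function(rel, top_k = Inf) {
  o <- order(-rel$mean_relevance, rel$feature)
  out <- rel[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, n = min(top_k, nrow(out)))
}

#' Relevance bar chart
#'
#' @param rel a `relevance_report`.
#' @param top_k number of features shown.
#' @param path optional output file (SVG/PNG by extension).
#' @return a ggplot object, invisibly if written to file.
#' @export
plot_relevance <- function(rel, top_k = 25, path = NULL) {
  r <- rank_report(rel, top_k)
  r$feature <- factor(r$feature, levels = rev(r$feature))
  p <- ggplot2::ggplot(r, ggplot2::aes(x = .data$feature, y = .data$mean_relevance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_relevance - .data$sd_relevance,
      ymax = .data$mean_relevance + .data$sd_relevance), width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative increase in STDE") +
    ggplot2::theme_minimal()
  if (!is.null(path)) { ggplot2::ggsave(path, p, width = 7, height = 6); return(invisible(p)) }
  p
}
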