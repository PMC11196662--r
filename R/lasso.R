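#' Fit an L1 (LASSO) coefficient path over the candidate risk factors
#'
#' Standardises the eight candidate factors (zero mean, unit variance) and
#' fits an L1-penalised regression path with \pkg{glmnet} over a log-spaced
#' penalty grid running from `lambda_max` (smallest penalty with an empty
#' support) down to `lambda_max * lambda_min_ratio`.  The binomial family is
#' the default; a squared-error (`"gaussian"`) family is available for
#' analytic checks on orthonormal designs.
#'
#' @param data Labelled data set from [label_abnormal()] (or any data frame
#'   with the eight feature columns plus `abnormal`).
#' @param n_lambdas Number of penalties on the grid (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest penalty
#'   (default `1e-4`).
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param lambda Optional user-supplied penalty grid (decreasing).
#' @param standardize Standardise features before penalisation
#'   (default `TRUE`).
#' @param intercept Include an unpenalised intercept (default `TRUE`);
#'   `FALSE` is useful for analytic checks on orthonormal designs.
#' @return An object of class `"abtp_lasso"`: `lambda` (decreasing grid),
#'   `beta` (factors x penalties coefficient matrix on the standardised
#'   scale), `entry_lambda` (largest penalty at which each factor is active),
#'   `dropped` (constant columns removed, with a warning), `family`,
#'   `selected_lambda` (`NA` until [select_lambda_cv()] is run).
#' @seealso [rank_factors()], [select_lambda_cv()]
#' @export
fit_lasso_path <- function(data, n_lambdas = 100, lambda_min_ratio = 1e-4,
                           family = c("binomial", "gaussian"),
                           lambda = NULL, standardize = TRUE,
                           intercept = TRUE) {
  family <- match.arg(family)
  xy <- .lasso_design(data, family)
  x <- xy$x; y <- xy$y
  dropped <- character(0)
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    dropped <- colnames(x)[const]
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  if (standardize) x <- scale(x)

  fit <- glmnet::glmnet(x, y, family = family, alpha = 1,
                        nlambda = n_lambdas,
                        lambda.min.ratio = lambda_min_ratio,
                        lambda = lambda, intercept = intercept,
                        standardize = FALSE, thresh = 1e-12)
  beta <- as.matrix(fit$beta)
  entry <- apply(abs(beta) > 1e-8, 1, function(active) {
    if (any(active)) fit$lambda[which(active)[1L]] else -Inf
  })
  structure(list(lambda = fit$lambda, beta = beta, entry_lambda = entry,
                 dropped = dropped, family = family,
                 selected_lambda = NA_real_, glmnet = fit,
                 x = x, y = y),
            class = "abtp_lasso")
}

.lasso_design <- function(data, family) {
  if (is.list(data) && !is.data.frame(data) &&
      all(c("x", "y") %in% names(data)))
    return(list(x = as.matrix(data$x), y = data$y))
  stopifnot(is.data.frame(data))
  miss <- setdiff(c(.abtp_features, "abnormal"), names(data))
  if (length(miss))
    stop("labelled data set is missing column(s): ",
         paste(miss, collapse = ", "))
  y <- data$abnormal
  if (family == "binomial" && length(unique(y)) < 2L)
    stop("both outcome classes must be present")
  list(x = as.matrix(data[.abtp_features]), y = y)
}

#' Rank candidate risk factors by LASSO path entry order
#'
#' Orders factors by the penalty at which each coefficient first becomes
#' non-zero along the path: a factor entering at a larger penalty survives
#' stronger shrinkage and is ranked as more important.  Ties are broken by
#' the absolute standardised coefficient at `selected_lambda` (default: the
#' path's CV-selected penalty if set, otherwise the smallest penalty on the
#' grid), then by column order.
#'
#' @param path An `"abtp_lasso"` object from [fit_lasso_path()].
#' @param selected_lambda Penalty used for tie-breaking coefficients.
#' @return Character vector of factor names, most important first (dropped
#'   constant columns, if any, come last).
#' @examples
#' herd <- generate_herd(herd_config(seed = 3))
#' d <- label_abnormal(herd)
#' rank_factors(fit_lasso_path(d))
#' @export
rank_factors <- function(path, selected_lambda = NULL) {
  stopifnot(inherits(path, "abtp_lasso"))
  if (is.null(selected_lambda))
    selected_lambda <- if (is.finite(path$selected_lambda))
      path$selected_lambda else min(path$lambda)
  j <- which.min(abs(path$lambda - selected_lambda))
  mag <- abs(path$beta[, j])
  ord <- order(-path$entry_lambda, -mag, seq_along(path$entry_lambda))
  c(rownames(path$beta)[ord], path$dropped)
}

#' Select the LASSO penalty by stratified cross-validation
#'
#' K-fold cross-validation of the binomial deviance over the full-data
#' penalty grid, with folds stratified by outcome class and assigned from a
#' fixed seed, so the selection is deterministic.  The fold loop is explicit
#' (each fold refits the \pkg{glmnet} path on the training split and scores
#' held-out deviance), which also permits the 2-fold case.
#'
#' @param data Labelled data set (as for [fit_lasso_path()]).
#' @param folds Number of folds (>= 2, default 10).
#' @param seed Integer seed for the fold assignment.
#' @param n_lambdas,lambda_min_ratio Passed to the path construction.
#' @return The penalty minimising mean cross-validated deviance, with the
#'   per-lambda deviance table as attribute `"cv"`.
#' @export
select_lambda_cv <- function(data, folds = 10, seed = 1,
                             n_lambdas = 100, lambda_min_ratio = 1e-4) {
  if (folds < 2) stop("'folds' must be >= 2")
  xy <- .lasso_design(data, "binomial")
  x <- scale(xy$x); y <- xy$y
  if (min(table(y)) < folds)
    stop("'folds' exceeds the size of the smaller outcome class")
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         nlambda = n_lambdas,
                         lambda.min.ratio = lambda_min_ratio,
                         standardize = FALSE, thresh = 1e-10)
  lambda <- full$lambda
  dev <- matrix(NA_real_, folds, length(lambda))
  eps <- 1e-12
  for (k in seq_len(folds)) {
    tr <- foldid != k
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 1, lambda = lambda,
                          standardize = FALSE, thresh = 1e-10)
    pr <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response",
                         s = lambda)
    pr <- pmin(pmax(pr, eps), 1 - eps)
    dev[k, ] <- -2 * colMeans(y[!tr] * log(pr) +
                                (1 - y[!tr]) * log1p(-pr))
  }
  mdev <- colMeans(dev)
  structure(lambda[which.min(mdev)],
            cv = data.frame(lambda = lambda, deviance = mdev))
}

#' @export
print.abtp_lasso <- function(x, ...) {
  cat(sprintf("LASSO path (%s): %d factors, %d penalties in [%.3g, %.3g]\n",
              x$family, nrow(x$beta), length(x$lambda),
              min(x$lambda), max(x$lambda)))
  cat("Entry order:", paste(rank_factors(x), collapse = " > "), "\n")
  invisible(x)
}

#' Plot a LASSO coefficient path
#'
#' Standardised coefficient trajectories against `log(lambda)`, mirroring
#' the usual coefficient-convergence display.
#'
#' @param x An `"abtp_lasso"` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.abtp_lasso <- function(x, ...) {
  graphics::matplot(log(x$lambda), t(x$beta), type = "l", lty = 1,
                    xlab = "log(lambda)",
                    ylab = "standardised coefficient",
                    main = "LASSO coefficient path", ...)
  graphics::legend("topright", legend = rownames(x$beta),
                   col = seq_len(nrow(x$beta)), lty = 1, cex = 0.7)
  invisible(x)
}
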