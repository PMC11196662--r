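#' Fit an abnormal body temperature probability model
#'
#' Fits one of the four sigmoid ABTP curve families ([prob_lkb()],
#' [prob_logistic()], [prob_schultheiss()], [prob_poisson()]) to a binary
#' abnormal-temperature outcome by maximum likelihood.  Each family has two
#' free parameters: the location `tn50` (risk-factor value at 50%
#' probability) and a family-specific shape.
#'
#' The optimiser is deterministic: a coarse grid search — `tn50` over the
#' observed range of the predictor, the shape over a log-spaced grid inside
#' its documented box — followed by Nelder-Mead refinement from the best grid
#' point.  The refined optimum is never allowed to fall below the best grid
#' value, and `converged` records the optimiser status.
#'
#' @param formula A two-sided formula `outcome ~ factor` with a binary (0/1
#'   or logical) outcome and a single quantitative predictor, typically
#'   `abnormal ~ thi`.
#' @param data A data frame containing the variables of `formula`.
#' @param family Curve family: `"lkb"` (default), `"logistic"`,
#'   `"schultheiss"` or `"poisson"`.
#' @param grid_size Number of grid points per parameter in the coarse search
#'   (default 50, i.e. a 50 x 50 grid).
#' @param eps Probability clipping constant used in the likelihood.
#' @param control Passed to [stats::optim()] (Nelder-Mead); `reltol` defaults
#'   to `1e-8`.
#' @return An object of class `"abtp"`: a list with elements `params`
#'   ([abtp_params()]), `coefficients`, `log_likelihood`, `n_parameters` (2),
#'   `converged`, `n_obs`, `data`, `grid_log_likelihood` and `call`.  Methods
#'   are provided for `print`, `summary`, `coef`, `predict`, `logLik`, `AIC`,
#'   `simulate`, `residuals` and `plot`.
#' @seealso [abtp_ttq()] for TT50/TT20 inversion, [evaluate_abtp()] for the
#'   model-comparison battery.
#' @examples
#' herd <- generate_herd(herd_config(seed = 42))
#' d <- label_abnormal(herd)
#' fit <- abtp(abnormal ~ thi, data = d, family = "lkb")
#' summary(fit)
#' abtp_ttq(fit, 0.5)
#' @export
abtp <- function(formula, data, family = "lkb", grid_size = 50,
                 eps = 1e-12, control = list()) {
  family <- .match_family(family)
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("'formula' must have exactly one predictor, e.g. abnormal ~ thi")
  y <- mf[[1L]]
  if (is.logical(y)) y <- as.numeric(y)
  n <- mf[[2L]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present to fit an ABTP model")
  if (any(!is.finite(n))) stop("predictor contains non-finite values")
  if (family %in% c("schultheiss", "poisson") && any(n <= 0))
    stop(sprintf("the %s family requires a positive risk factor", family))

  fit <- .fit_abtp(n, y, family, grid_size = grid_size, eps = eps,
                   control = control)
  fit$call <- match.call()
  fit$var_names <- names(mf)
  fit
}

# core fitter on raw vectors; deterministic
.fit_abtp <- function(n, y, family, grid_size = 50, eps = 1e-12,
                      control = list()) {
  bounds <- .abtp_shape_bounds[[family]]
  tn50_box <- range(n)
  if (tn50_box[1] <= 0) tn50_box[1] <- min(n[n > 0], 1e-3)
  tn50_grid <- seq(tn50_box[1], tn50_box[2], length.out = grid_size)
  shape_grid <- exp(seq(log(bounds[1]), log(bounds[2]),
                        length.out = grid_size))

  ll_grid <- .abtp_grid_ll(family, n, y, tn50_grid, shape_grid, eps)
  best <- arrayInd(which.max(ll_grid), dim(ll_grid))
  grid_ll <- ll_grid[best]
  start <- c(tn50_grid[best[1]], log(shape_grid[best[2]]))

  negll <- function(par) {
    t50 <- par[1]; shape <- exp(par[2])
    if (!is.finite(t50) || t50 < tn50_box[1] || t50 > tn50_box[2] ||
        shape < bounds[1] || shape > bounds[2]) return(1e10)
    -.abtp_ll_one(family, n, y, t50, shape, eps)
  }
  ctrl <- utils::modifyList(list(reltol = 1e-8, maxit = 2000), control)
  opt <- stats::optim(start, negll, method = "Nelder-Mead", control = ctrl)

  refined_ll <- -opt$value
  if (refined_ll >= grid_ll) {
    tn50 <- opt$par[1]; shape <- exp(opt$par[2]); ll <- refined_ll
  } else {                      # keep the grid optimum (cannot get worse)
    tn50 <- start[1]; shape <- exp(start[2]); ll <- grid_ll
  }
  params <- abtp_params(family, tn50 = tn50, shape = shape)
  coefs <- c(tn50 = tn50, shape = shape)
  names(coefs)[2] <- .abtp_shape_name[[family]]

  structure(list(
    family = family,
    params = params,
    coefficients = coefs,
    log_likelihood = ll,
    n_parameters = 2L,
    converged = opt$convergence == 0L,
    n_obs = length(y),
    data = list(n = n, y = y),
    grid_log_likelihood = grid_ll,
    optim = list(convergence = opt$convergence, counts = opt$counts),
    eps = eps
  ), class = "abtp")
}

# vectorised grid log-likelihood: matrix tn50 x shape
.abtp_grid_ll <- function(family, n, y, tn50_grid, shape_grid, eps) {
  nt <- length(tn50_grid); ns <- length(shape_grid)
  out <- matrix(NA_real_, nt, ns)
  for (j in seq_len(ns)) {
    s <- shape_grid[j]
    P <- switch(family,
      lkb = stats::pnorm(outer(n, tn50_grid, function(x, t) (x - t) / (s * t))),
      logistic = stats::plogis(outer(n, tn50_grid, function(x, t) s * (x - t))),
      schultheiss = stats::plogis(outer(log(n), log(tn50_grid), "-") * s),
      poisson = 2^(-exp(exp(1) * s * (1 - outer(n, tn50_grid, "/")))))
    P <- pmin(pmax(P, eps), 1 - eps)
    out[, j] <- colSums(y * log(P) + (1 - y) * log1p(-P))
  }
  out
}

.abtp_ll_one <- function(family, n, y, tn50, shape, eps) {
  p <- switch(family,
    lkb = prob_lkb(n, tn50, shape),
    logistic = stats::plogis(shape * (n - tn50)),
    schultheiss = prob_schultheiss(n, tn50, shape),
    poisson = prob_poisson(n, tn50, shape))
  bernoulli_loglik(y, p, eps)
}

#' Invert a fitted ABTP curve to the TTq threshold
#'
#' Returns the risk-factor value (e.g. THI) at which the curve predicts
#' probability `q`; `q = 0.5` gives TT50 (identically `tn50`), `q = 0.2`
#' gives TT20.  Closed forms are used for the LKB, logistic and Schultheiss
#' families; the Poisson curve is inverted by bracketed root-finding.
#'
#' @param object A fitted `"abtp"` model or an [abtp_params()] object.
#' @param q Target probability in (0, 1); may be a vector.
#' @return Risk-factor value(s) at probability `q`.
#' @examples
#' p <- abtp_params("lkb", tn50 = 75, shape = 0.05)
#' abtp_ttq(p, c(0.2, 0.5))
#' @export
abtp_ttq <- function(object, q) {
  params <- if (inherits(object, "abtp")) object$params else object
  stopifnot(inherits(params, "abtp_params"))
  if (any(q <= 0 | q >= 1)) stop("'q' must lie strictly inside (0, 1)")
  tn50 <- params$tn50; shape <- params$shape
  switch(params$family,
    lkb = {
      f <- 1 + shape * stats::qnorm(q)
      if (any(f <= 0))
        stop("'q' too small for the LKB curve: 1 + m * qnorm(q) <= 0")
      tn50 * f
    },
    logistic = tn50 + stats::qlogis(q) / shape,
    schultheiss = tn50 * (q / (1 - q))^(1 / shape),
    poisson = vapply(q, function(qi) {
      stats::uniroot(function(x) prob_poisson(x, tn50, shape) - qi,
                     lower = tn50 / 100, upper = tn50 * 100,
                     tol = 1e-10)$root
    }, numeric(1)))
}

#' @export
print.abtp <- function(x, digits = 4, ...) {
  cat(sprintf("ABTP model (%s family), n = %d\n", x$family, x$n_obs))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood: %.*f   AIC: %.*f   converged: %s\n",
              digits, x$log_likelihood, digits, stats::AIC(x),
              x$converged))
  invisible(x)
}

#' @export
summary.abtp <- function(object, ...) {
  tt50 <- abtp_ttq(object, 0.5)
  tt20 <- tryCatch(abtp_ttq(object, 0.2), error = function(e) NA_real_)
  extra <- NULL
  if (object$family == "logistic") {
    beta1 <- object$coefficients[["beta1"]]
    extra <- c(beta0 = -object$coefficients[["tn50"]] * beta1,
               gamma50 = beta1 * tt50 / 4)   # normalised slope at 50%
  }
  structure(list(fit = object, tt50 = tt50, tt20 = tt20, extra = extra,
                 aic = stats::AIC(object)),
            class = "summary.abtp")
}

#' @export
print.summary.abtp <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("TT50: %.*f   TT20: %.*f\n", digits, x$tt50, digits, x$tt20))
  if (!is.null(x$extra)) {
    cat("Derived logistic quantities:\n")
    print(round(x$extra, digits))
  }
  invisible(x)
}

#' @export
coef.abtp <- function(object, ...) object$coefficients

#' @export
logLik.abtp <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.abtp <- function(object, ...) object$n_obs

#' Predict ABTP probabilities from a fitted model
#'
#' @param object A fitted `"abtp"` model.
#' @param newdata Numeric vector of risk-factor values, or a data frame
#'   containing the predictor column used at fit time.  Defaults to the
#'   training values.
#' @param ... Unused.
#' @return Vector of predicted probabilities.
#' @export
predict.abtp <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$data$n
       else if (is.data.frame(newdata)) newdata[[object$var_names[2L]]]
       else newdata
  if (is.null(n)) stop("'newdata' does not contain the model predictor")
  abtp_prob(object$params, n)
}

#' @export
fitted.abtp <- function(object, ...) abtp_prob(object$params, object$data$n)

#' @export
residuals.abtp <- function(object,
                           type = c("response", "pearson", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$data$y
  p <- fitted(object)
  switch(type,
    response = y - p,
    pearson = (y - p) / sqrt(p * (1 - p)),
    deviance = {
      pc <- pmin(pmax(p, object$eps), 1 - object$eps)
      sign(y - p) * sqrt(-2 * (y * log(pc) + (1 - y) * log1p(-pc)))
    })
}

#' Simulate binary outcomes from a fitted ABTP model
#'
#' Draws Bernoulli outcomes at the model's training risk-factor values (or at
#' `newdata`) with success probability given by the fitted curve.
#'
#' @param object A fitted `"abtp"` model.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed; restores the RNG state afterwards in
#'   the usual [stats::simulate()] convention.
#' @param newdata Optional risk-factor values to simulate at.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.abtp <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- predict(object, newdata = newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted ABTP curve
#'
#' Draws the fitted sigmoid over the observed risk-factor range with binned
#' empirical abnormality rates and a TT50 marker.
#'
#' @param x A fitted `"abtp"` model.
#' @param bins Number of equal-frequency bins for the empirical rates.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.abtp <- function(x, bins = 10, ...) {
  n <- x$data$n; y <- x$data$y
  grid <- seq(min(n), max(n), length.out = 200)
  graphics::plot(grid, abtp_prob(x$params, grid), type = "l", lwd = 2,
                 col = "steelblue", ylim = c(0, 1),
                 xlab = x$var_names[2L] %||% "risk factor",
                 ylab = "abnormal body temperature probability",
                 main = sprintf("ABTP curve (%s)", x$family), ...)
  br <- unique(stats::quantile(n, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) > 2) {
    g <- cut(n, br, include.lowest = TRUE)
    graphics::points(tapply(n, g, mean), tapply(y, g, mean), pch = 19)
  }
  tt50 <- abtp_ttq(x, 0.5)
  graphics::abline(v = tt50, h = 0.5, lty = 3, col = "grey40")
  graphics::mtext(sprintf("TT50 = %.2f", tt50), side = 3, adj = 1,
                  cex = 0.8)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
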