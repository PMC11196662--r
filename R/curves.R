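#' @keywords internal
"_PACKAGE"

#' ABTP curve families
#'
#' Names of the four sigmoid tolerance-curve families available for modelling
#' the abnormal body temperature probability (ABTP) as a function of a
#' quantitative risk factor (in this package usually the temperature-humidity
#' index, THI).
#'
#' @format Character vector of length four.
#' @export
abtp_families <- c("lkb", "logistic", "schultheiss", "poisson")

# shape-parameter names and search bounds per family; tn50 is always the
# location.  Bounds are the documented optimizer box, not hard limits of the
# mathematical curves.
.abtp_shape_name <- c(lkb = "m", logistic = "beta1", schultheiss = "k",
                      poisson = "gamma")
.abtp_shape_bounds <- list(lkb = c(0.005, 2), logistic = c(0.005, 5),
                           schultheiss = c(0.1, 200), poisson = c(0.05, 20))

.match_family <- function(family) {
  match.arg(tolower(family), abtp_families)
}

#' LKB (probit) abnormal-temperature probability
#'
#' Lyman-Kutcher-Burman probit tolerance curve: the standard normal CDF
#' evaluated at `u = (n - tn50) / (m * tn50)`.  `tn50` is the value of the
#' risk factor at which the probability is exactly 1/2 and `m` controls the
#' (relative) width of the transition.
#'
#' @param n Quantitative risk-factor values (e.g. THI).
#' @param tn50 Location parameter (> 0), factor value at 50% probability.
#' @param m Dimensionless slope parameter (> 0); smaller is steeper.
#' @return Probabilities in (0, 1), same length as `n`.
#' @examples
#' prob_lkb(75, tn50 = 75, m = 0.05)   # exactly 0.5
#' @export
prob_lkb <- function(n, tn50, m) {
  .check_pos(tn50, "tn50"); .check_pos(m, "m")
  stats::pnorm((n - tn50) / (m * tn50))
}

#' Logistic abnormal-temperature probability
#'
#' `1 / (1 + exp(-(beta0 + beta1 * n)))`, evaluated overflow-safely.  The 50%
#' point is `-beta0 / beta1`.
#'
#' @inheritParams prob_lkb
#' @param beta0 Intercept of the linear predictor.
#' @param beta1 Slope of the linear predictor (non-zero).
#' @return Probabilities, same length as `n`.
#' @examples
#' prob_logistic(75, beta0 = -22.5, beta1 = 0.30)  # 0.5
#' @export
prob_logistic <- function(n, beta0, beta1) {
  if (!is.finite(beta0) || !is.finite(beta1) || beta1 == 0)
    stop("'beta0' must be finite and 'beta1' finite and non-zero")
  stats::plogis(beta0 + beta1 * n)
}

#' Schultheiss (log-logistic) abnormal-temperature probability
#'
#' `1 / (1 + (tn50 / n)^k)`, a log-logistic sigmoid in the risk factor.
#' Computed on the log scale for numerical stability.
#'
#' @inheritParams prob_lkb
#' @param k Shape parameter (> 0); larger is steeper.
#' @return Probabilities in (0, 1), same length as `n`.
#' @export
prob_schultheiss <- function(n, tn50, k) {
  .check_pos(tn50, "tn50"); .check_pos(k, "k")
  if (any(n <= 0)) stop("'n' must be positive for the Schultheiss curve")
  stats::plogis(k * (log(n) - log(tn50)))
}

#' Poisson tolerance-curve abnormal-temperature probability
#'
#' `2^(-exp(e * gamma * (1 - n / tn50)))` with `e = exp(1)` at full machine
#' precision.  At `n = tn50` the inner exponential is 1 and the probability is
#' exactly `2^-1 = 0.5`, which is what defines `tn50`.
#'
#' @inheritParams prob_lkb
#' @param gamma Slope parameter (> 0); larger is steeper.
#' @return Probabilities in (0, 1), same length as `n`.
#' @export
prob_poisson <- function(n, tn50, gamma) {
  .check_pos(tn50, "tn50"); .check_pos(gamma, "gamma")
  2^(-exp(exp(1) * gamma * (1 - n / tn50)))
}

.check_pos <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name))
  invisible(x)
}

#' Construct a validated ABTP parameter set
#'
#' Bundles a curve family with its two parameters.  All families are stored as
#' (location `tn50`, family-specific shape); for the logistic family the
#' natural parameters are `beta0`, `beta1` and `tn50 = -beta0 / beta1` is
#' derived (or conversely `beta0 = -tn50 * beta1` when `tn50` is supplied).
#'
#' @param family One of `"lkb"`, `"logistic"`, `"schultheiss"`, `"poisson"`.
#' @param tn50 Location: risk-factor value at 50% probability (> 0).
#' @param shape Family shape parameter: `m` (lkb), `beta1` (logistic),
#'   `k` (schultheiss) or `gamma` (poisson).
#' @param beta0,beta1 Logistic natural parameters, alternative to
#'   `tn50`/`shape` for `family = "logistic"`.
#' @return An object of class `"abtp_params"`.
#' @examples
#' abtp_params("logistic", beta0 = -22.5, beta1 = 0.30)
#' abtp_params("lkb", tn50 = 75, shape = 0.05)
#' @export
abtp_params <- function(family, tn50 = NULL, shape = NULL,
                        beta0 = NULL, beta1 = NULL) {
  family <- .match_family(family)
  if (family == "logistic" && !is.null(beta0)) {
    if (is.null(beta1)) stop("'beta1' required with 'beta0'")
    shape <- beta1
    tn50 <- -beta0 / beta1
  }
  if (is.null(tn50) || is.null(shape))
    stop("supply 'tn50' and 'shape' (or 'beta0'/'beta1' for logistic)")
  if (!is.finite(tn50) || tn50 <= 0) stop("'tn50' must be positive")
  if (!is.finite(shape)) stop("'shape' must be finite")
  if (family == "logistic") {
    if (shape == 0) stop("'beta1' must be non-zero")
  } else if (shape <= 0) {
    stop(sprintf("'%s' must be positive", .abtp_shape_name[[family]]))
  }
  structure(list(family = family, tn50 = tn50, shape = shape),
            class = "abtp_params")
}

#' Evaluate an ABTP curve
#'
#' @param params An [abtp_params()] object.
#' @param n Risk-factor values at which to evaluate the curve.
#' @return Vector of probabilities.
#' @export
abtp_prob <- function(params, n) {
  stopifnot(inherits(params, "abtp_params"))
  switch(params$family,
    lkb = prob_lkb(n, params$tn50, params$shape),
    logistic = prob_logistic(n, -params$tn50 * params$shape, params$shape),
    schultheiss = prob_schultheiss(n, params$tn50, params$shape),
    poisson = prob_poisson(n, params$tn50, params$shape))
}

#' @export
print.abtp_params <- function(x, ...) {
  cat(sprintf("ABTP parameters (%s): tn50 = %.4f, %s = %.5f\n",
              x$family, x$tn50, .abtp_shape_name[[x$family]], x$shape))
  invisible(x)
}

#' Bernoulli log-likelihood of probabilistic forecasts
#'
#' `sum(y * log(p) + (1 - y) * log(1 - p))` in nats, with probabilities
#' clipped to `[eps, 1 - eps]` before taking logs so that degenerate forecasts
#' do not produce `-Inf`.
#'
#' @param y Binary 0/1 outcome vector.
#' @param p Predicted probabilities, same length as `y`.
#' @param eps Clipping constant, default `1e-12`.
#' @return Log-likelihood (a single non-positive number).
#' @export
bernoulli_loglik <- function(y, p, eps = 1e-12) {
  if (length(y) != length(p)) stop("'y' and 'p' must have equal length")
  if (!all(y %in% c(0, 1))) stop("'y' must be binary 0/1")
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log1p(-p))
}
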