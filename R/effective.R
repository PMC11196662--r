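#' Construct an LKB effective-index model
#'
#' The effective-index model couples the quantitative risk factor (THI) with
#' body temperature through a power law: the 50%-probability factor value
#' declines with body temperature as `Tn50(temp) = tn50_at_unit * temp^-c`,
#' and an observed factor value is mapped onto an effective body temperature
#' `temp_eff = temp * (n / n_ref)^-c`.  The abnormality probability is the
#' LKB probit `pnorm(u)` with
#' `u = (num - tn50_at_unit * temp_eff^-c) / (m * tn50_at_unit * temp_eff^-c)`,
#' where the numerator term `num` is the reference value `n_ref`
#' (`numerator = "reference"`, the default) or the observed factor value
#' (`numerator = "observed"`).  With the observed numerator the surface is
#' increasing in the factor at fixed temperature, which is the orientation
#' under which the 20% iso-contour lies below the 50% one.
#'
#' @param tn50_at_unit `Tn50(1)`: the 50% factor value extrapolated to unit
#'   body temperature (> 0).
#' @param c Power-law exponent (> 0; 0 is accepted as the decoupled
#'   boundary case).
#' @param m LKB slope parameter (> 0).
#' @param n_ref Reference value of the quantitative factor (> 0).
#' @param temp_ref Reference body temperature (degC), used only as fitting
#'   metadata.
#' @param numerator `"reference"` or `"observed"` (see Details).
#' @return An object of class `"abtp_eff"`.
#' @export
eff_index_model <- function(tn50_at_unit, c, m, n_ref,
                            temp_ref = NA_real_,
                            numerator = c("reference", "observed")) {
  numerator <- match.arg(numerator)
  if (!is.finite(tn50_at_unit) || tn50_at_unit <= 0)
    stop("'tn50_at_unit' must be positive")
  if (!is.finite(c) || c < 0) stop("'c' must be >= 0")
  if (!is.finite(m) || m <= 0) stop("'m' must be positive")
  if (!is.finite(n_ref) || n_ref <= 0) stop("'n_ref' must be positive")
  structure(list(tn50_at_unit = tn50_at_unit, c = c, m = m,
                 n_ref = n_ref, temp_ref = temp_ref,
                 numerator = numerator),
            class = "abtp_eff")
}

#' Power-law tolerance threshold as a function of body temperature
#'
#' `Tn50(temp) = tn50_at_unit * temp^-c`: the factor value at 50%
#' abnormality probability for an animal at body temperature `temp`.
#'
#' @param temp Body temperature(s) in degC (> 0).
#' @param model An `"abtp_eff"` model.
#' @return Tn50 value(s) on the risk-factor scale.
#' @examples
#' m <- eff_index_model(100, c = 0.08, m = 0.05, n_ref = 75)
#' tn50_power_law(38.32, m)   # about 74.69
#' @export
tn50_power_law <- function(temp, model) {
  stopifnot(inherits(model, "abtp_eff"))
  if (any(temp <= 0)) stop("'temp' must be positive")
  model$tn50_at_unit * temp^(-model$c)
}

#' Effective body temperature under the power-law normalisation
#'
#' `temp_eff = temp_i * (n_i / n_ref)^-c`.  When the observed factor equals
#' the reference value the effective temperature is the observed temperature
#' exactly.
#'
#' @param temp_i Observed body temperature(s) in degC (> 0).
#' @param n_i Observed factor value(s) (> 0).
#' @param model An `"abtp_eff"` model.
#' @return Effective temperature(s) in degC.
#' @export
effective_temperature <- function(temp_i, n_i, model) {
  stopifnot(inherits(model, "abtp_eff"))
  if (any(n_i <= 0)) stop("'n_i' must be positive")
  if (any(temp_i <= 0)) stop("'temp_i' must be positive")
  temp_i * (n_i / model$n_ref)^(-model$c)
}

#' LKB effective-index abnormality probability
#'
#' Evaluates the probit surface at an effective temperature:
#' `pnorm((num - t50e) / (m * t50e))` with
#' `t50e = tn50_at_unit * temp_eff^-c` and `num` the reference factor value
#' (or `n` when supplied, for the observed-numerator variant).
#'
#' @param temp_eff Effective body temperature(s), degC (> 0).
#' @param model An `"abtp_eff"` model.
#' @param n Factor value(s) for the numerator; defaults to `model$n_ref`.
#' @return Probabilities in (0, 1).
#' @export
lkb_eff_prob <- function(temp_eff, model, n = NULL) {
  stopifnot(inherits(model, "abtp_eff"))
  if (any(temp_eff <= 0)) stop("'temp_eff' must be positive")
  t50e <- model$tn50_at_unit * temp_eff^(-model$c)
  num <- if (is.null(n)) model$n_ref else n
  stats::pnorm((num - t50e) / (model$m * t50e))
}

# full surface: probability at observed (thi, temp)
.eff_surface_prob <- function(thi, temp, model) {
  teff <- effective_temperature(temp, thi, model)
  n <- if (model$numerator == "observed") thi else NULL
  lkb_eff_prob(teff, model, n = n)
}

#' Fit the LKB effective-index model by maximum likelihood
#'
#' Joint MLE of `(tn50_at_unit, c, m)` from per-animal triples of risk
#' factor, body temperature and binary abnormality outcome.  The search is
#' a deterministic coarse grid (the 50% level at the reference temperature
#' over the observed factor range, `c` and `m` over log-spaced boxes)
#' followed by Nelder-Mead refinement; internally the location is
#' parameterised as `tn50_at_ref = tn50_at_unit * temp_ref^-c` (the
#' 50%-level at the mean body temperature), which decorrelates the location
#' from the exponent.
#'
#' @param formula `outcome ~ factor + body_temperature`, e.g.
#'   `abnormal ~ thi + eye_temp`.
#' @param data Data frame containing the formula variables.
#' @param n_ref Reference factor value; defaults to the mean observed
#'   factor (the herd-mean condition).
#' @param numerator `"reference"` (verbatim probit form, default) or
#'   `"observed"`.
#' @param grid_size Grid points as `c(location, exponent, slope)`,
#'   default `c(12, 8, 8)`.
#' @param eps Probability clipping constant.
#' @param control Passed to [stats::optim()].
#' @return A fitted `"abtp_eff"` model with additional elements
#'   `log_likelihood`, `converged`, `n_obs`, `data` and `var_names`.
#' @examples
#' truth <- eff_index_model(75 * 38.3^0.8, c = 0.8, m = 0.04, n_ref = 75)
#' set.seed(1)
#' d <- data.frame(thi = runif(2000, 55, 95), temp = runif(2000, 33, 45))
#' d$abnormal <- rbinom(2000, 1,
#'   lkb_eff_prob(effective_temperature(d$temp, d$thi, truth), truth))
#' fit <- abtp_eff(abnormal ~ thi + temp, d, n_ref = 75)
#' coef(fit)
#' @export
abtp_eff <- function(formula, data, n_ref = NULL,
                     numerator = c("reference", "observed"),
                     grid_size = c(12, 8, 8), eps = 1e-12,
                     control = list()) {
  numerator <- match.arg(numerator)
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 3L)
    stop("'formula' must be outcome ~ factor + body_temperature")
  y <- mf[[1L]]; if (is.logical(y)) y <- as.numeric(y)
  thi <- mf[[2L]]; temp <- mf[[3L]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (any(thi <= 0) || any(temp <= 0))
    stop("factor and body temperature must be positive")
  if (is.null(n_ref)) n_ref <- mean(thi)
  temp_ref <- mean(temp)
  lt <- log(temp)

  # negative log-likelihood in (tn50_at_ref, log c, log m)
  num_obs <- numerator == "observed"
  nll <- function(par) {
    t50r <- par[1]; cc <- exp(par[2]); m <- exp(par[3])
    if (!is.finite(t50r) || t50r <= 0 ||
        cc < 0.002 || cc > 4 || m < 0.001 || m > 4) return(1e10)
    # t50e = t50r * (teff/temp_ref)^-c, teff = temp * (thi/n_ref)^-c
    w <- exp(-cc * (lt - log(temp_ref)) + cc^2 * log(thi / n_ref))
    t50e <- t50r * w
    num <- if (num_obs) thi else n_ref
    p <- stats::pnorm((num - t50e) / (m * t50e))
    -bernoulli_loglik(y, p, eps)
  }

  t50_grid <- seq(min(thi), max(thi), length.out = grid_size[1])
  c_grid <- exp(seq(log(0.01), log(2), length.out = grid_size[2]))
  m_grid <- exp(seq(log(0.005), log(2), length.out = grid_size[3]))
  best <- NULL; bv <- Inf
  for (cc in c_grid) for (m in m_grid) for (t50r in t50_grid) {
    v <- nll(c(t50r, log(cc), log(m)))
    if (v < bv) { bv <- v; best <- c(t50r, log(cc), log(m)) }
  }
  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 5000), control)
  opt <- stats::optim(best, nll, method = "Nelder-Mead", control = ctrl)
  opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead", control = ctrl)
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$value > bv) {            # never fall below the grid optimum
    opt$par <- best; opt$value <- bv
  }
  cc <- exp(opt$par[2]); m <- exp(opt$par[3])
  model <- eff_index_model(tn50_at_unit = opt$par[1] * temp_ref^cc,
                           c = cc, m = m, n_ref = n_ref,
                           temp_ref = temp_ref, numerator = numerator)
  model$log_likelihood <- -opt$value
  model$converged <- opt$convergence == 0L
  model$n_obs <- length(y)
  model$data <- list(thi = thi, temp = temp, y = y)
  model$var_names <- names(mf)
  model$call <- match.call()
  model
}

#' @export
print.abtp_eff <- function(x, digits = 4, ...) {
  cat("LKB effective-index model\n")
  cat(sprintf("  tn50_at_unit = %.*f, c = %.*f, m = %.*f\n",
              digits, x$tn50_at_unit, digits, x$c, digits, x$m))
  cat(sprintf("  n_ref = %.*f, numerator = %s\n", digits, x$n_ref,
              x$numerator))
  if (!is.null(x$log_likelihood))
    cat(sprintf("  log-likelihood: %.*f (n = %d, converged: %s)\n",
                digits, x$log_likelihood, x$n_obs, x$converged))
  invisible(x)
}

#' @export
coef.abtp_eff <- function(object, ...) {
  c(tn50_at_unit = object$tn50_at_unit, c = object$c, m = object$m)
}

#' @export
logLik.abtp_eff <- function(object, ...) {
  if (is.null(object$log_likelihood)) stop("model was not fitted")
  structure(object$log_likelihood, df = 3L, nobs = object$n_obs,
            class = "logLik")
}

#' Predict abnormality probabilities from an effective-index model
#'
#' @param object An `"abtp_eff"` model.
#' @param newdata Data frame with the factor and body-temperature columns
#'   used at fit time (or columns `thi` and `temp`).  Defaults to the
#'   training data.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.abtp_eff <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$data)) stop("no training data stored; give 'newdata'")
    return(.eff_surface_prob(object$data$thi, object$data$temp, object))
  }
  nm <- object$var_names[-1L] %||% c("thi", "temp")
  if (!all(nm %in% names(newdata))) nm <- c("thi", "temp")
  .eff_surface_prob(newdata[[nm[1L]]], newdata[[nm[2L]]], object)
}

#' Iso-probability contour of the effective-index surface
#'
#' For each body temperature on `temp_grid`, finds the factor value (THI) at
#' which the model's abnormality probability equals `q`, by bracketed
#' root-finding (bisection refinement to `tol`).  Grid points where `q` is
#' not reachable inside `thi_bracket` are reported with `ok = FALSE` and an
#' `NA` factor value.
#'
#' @param model An `"abtp_eff"` model.
#' @param q Target probability in (0, 1).
#' @param temp_grid Body temperatures (degC) at which to trace the contour.
#' @param thi_bracket Search interval for the factor value.
#' @param tol Root tolerance on the factor scale (default `1e-8`).
#' @return Data frame with columns `temp`, `thi`, `ok`.
#' @export
iso_probability_contour <- function(model, q,
                                    temp_grid = seq(36, 41, by = 0.1),
                                    thi_bracket = c(30, 130),
                                    tol = 1e-8) {
  stopifnot(inherits(model, "abtp_eff"))
  if (length(q) != 1L || q <= 0 || q >= 1)
    stop("'q' must be a single probability in (0, 1)")
  thi <- vapply(temp_grid, function(tt) {
    f <- function(n) .eff_surface_prob(n, tt, model) - q
    lo <- f(thi_bracket[1]); hi <- f(thi_bracket[2])
    if (!is.finite(lo) || !is.finite(hi) || sign(lo) == sign(hi))
      return(NA_real_)
    stats::uniroot(f, interval = thi_bracket, tol = tol)$root
  }, numeric(1))
  data.frame(temp = temp_grid, thi = thi, ok = !is.na(thi))
}

#' Plot effective-index iso-probability contours with triage guides
#'
#' Draws the 50% and 20% contours in the (THI, body temperature) plane
#' together with the triage band boundaries and the THI alert line.
#'
#' @param x A fitted `"abtp_eff"` model.
#' @param q Probabilities to contour (default 0.5 and 0.2).
#' @param temp_grid Body-temperature grid.
#' @param bands A [triage_bands()] object for the guide lines.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.abtp_eff <- function(x, q = c(0.5, 0.2),
                          temp_grid = seq(36, 41, by = 0.05),
                          bands = triage_bands(), ...) {
  cons <- lapply(q, iso_probability_contour, model = x,
                 temp_grid = temp_grid)
  rng <- range(unlist(lapply(cons, function(d) d$thi)), na.rm = TRUE)
  graphics::plot(NA, xlim = rng + c(-2, 2), ylim = range(temp_grid),
                 xlab = "THI", ylab = "body temperature (degC)",
                 main = "effective-index iso-probability contours", ...)
  for (i in seq_along(cons))
    graphics::lines(cons[[i]]$thi, cons[[i]]$temp, lwd = 2, col = i + 1)
  graphics::abline(h = c(bands$normal_below, bands$observe_upper),
                   lty = 3, col = "grey40")
  graphics::abline(v = bands$thi_alert, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = sprintf("q = %.2f", q),
                   col = seq_along(q) + 1, lwd = 2, cex = 0.8)
  invisible(x)
}
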