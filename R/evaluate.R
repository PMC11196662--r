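#' AUC with DeLong 95% confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability (ties credited 1/2), with an analytic DeLong 95% confidence
#' interval.  Wraps \pkg{pROC}.
#'
#' @param y Binary 0/1 outcomes; both classes must be present.
#' @param p Predicted probabilities (or any monotone score).
#' @return Named numeric vector `c(auc, ci_low, ci_high)`.
#' @examples
#' auc_with_ci(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
#' @export
auc_with_ci <- function(y, p) {
  if (length(y) != length(p)) stop("'y' and 'p' must have equal length")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  roc <- pROC::roc(response = y, predictor = p, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  ci <- suppressWarnings(
    as.numeric(pROC::ci.auc(roc, method = "delong", conf.level = 0.95)))
  c(auc = auc, ci_low = ci[1], ci_high = ci[3])
}

#' Classification accuracy at a probability cutoff
#'
#' Predictions are abnormal when the probability strictly exceeds the
#' threshold (`p > threshold`, default 0.5); accuracy is the fraction of
#' agreements with `y`.
#'
#' @inheritParams auc_with_ci
#' @param threshold Probability cutoff, default 0.5.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_at <- function(y, p, threshold = 0.5) {
  if (length(y) != length(p)) stop("'y' and 'p' must have equal length")
  mean(as.integer(p > threshold) == y)
}

#' Brier score
#'
#' Mean squared difference between probabilistic forecasts and the binary
#' outcomes; 0 is perfect, a constant 0.5 forecast scores 0.25.
#'
#' @inheritParams auc_with_ci
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(y, p) {
  if (length(y) != length(p)) stop("'y' and 'p' must have equal length")
  mean((p - y)^2)
}

#' AIC differences relative to a baseline model
#'
#' `delta_aic[i] = aic[i] - aic[baseline]`; the baseline entry is `NA`
#' (conventionally rendered as a dash in comparison tables).
#'
#' @param aic Named numeric vector of AIC values.
#' @param baseline Name of the reference model (default `"LKB"`; matched
#'   case-insensitively).
#' @return Named numeric vector of the same length, baseline entry `NA`.
#' @examples
#' delta_aic(c(LKB = 361.28, Logistic = 361.60,
#'             Schultheiss = 361.56, Poisson = 362.22))
#' @export
delta_aic <- function(aic, baseline = "LKB") {
  if (is.null(names(aic))) stop("'aic' must be a named vector")
  i <- match(tolower(baseline), tolower(names(aic)))
  if (is.na(i)) stop(sprintf("baseline model '%s' not found", baseline))
  out <- aic - aic[[i]]
  out[i] <- NA_real_
  out
}

# equal-frequency probability bins (stable under ties); returns integer
# bin id per observation
.prob_bins <- function(p, bins) {
  ord <- order(p)                      # stable
  id <- integer(length(p))
  id[ord] <- ceiling(seq_along(p) / (length(p) / bins))
  pmin(id, bins)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Splits observations into `bins` equal-frequency groups by sorted
#' predicted probability and compares observed event counts `O_g` with
#' expected counts `E_g = sum(p)` per group:
#' `X2 = sum((O - E)^2 / (E * (1 - E / n_g)))`, referred to a chi-square
#' distribution with `bins - 2` degrees of freedom.  A p-value above 0.05
#' indicates no detectable miscalibration.  Groups with zero expected
#' variance are merged with their neighbour (with a message).
#'
#' @inheritParams auc_with_ci
#' @param bins Number of groups (default 10); at least 3 are required for
#'   positive degrees of freedom.
#' @return List with `statistic`, `df`, `p_value` and the per-bin `table`
#'   (`n`, `observed`, `expected`, `mean_p`).
#' @export
hosmer_lemeshow <- function(y, p, bins = 10) {
  if (length(y) != length(p)) stop("'y' and 'p' must have equal length")
  if (length(y) < bins) stop("need at least 'bins' observations")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  id <- .prob_bins(p, bins)
  tab <- data.frame(
    n = as.vector(tapply(y, id, length)),
    observed = as.vector(tapply(y, id, sum)),
    expected = as.vector(tapply(p, id, sum)),
    mean_p = as.vector(tapply(p, id, mean)))
  # merge degenerate groups (zero expected variance) into the neighbour
  degen <- function(t) t$expected <= 0 | t$expected >= t$n
  while (any(degen(tab)) && nrow(tab) > 1L) {
    g <- which(degen(tab))[1L]
    nb <- if (g == 1L) 2L else g - 1L
    message("merging degenerate probability group with its neighbour")
    tab$n[nb] <- tab$n[nb] + tab$n[g]
    tab$observed[nb] <- tab$observed[nb] + tab$observed[g]
    tab$expected[nb] <- tab$expected[nb] + tab$expected[g]
    tab <- tab[-g, , drop = FALSE]
  }
  df <- nrow(tab) - 2L
  if (df < 1L) stop("fewer than 3 usable groups: degrees of freedom < 1")
  stat <- sum((tab$observed - tab$expected)^2 /
              (tab$expected * (1 - tab$expected / tab$n)))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab)
}

#' Calibration curve with weighted slope and intercept
#'
#' Bins observations into `bins` equal-frequency groups by predicted
#' probability and regresses the per-bin observed event rate on the per-bin
#' mean prediction by least squares weighted with the bin counts.  A
#' perfectly calibrated model gives slope 1 and intercept 0 (the 45-degree
#' line).  The count-weighted correlation between bin-observed and
#' bin-predicted rates is reported as well.  When all bins share one
#' predicted value the regression is undefined and `degenerate = TRUE` is
#' returned with `NA` slope.
#'
#' @inheritParams hosmer_lemeshow
#' @return List with `table` (per-bin `n`, `mean_p`, `obs_rate`), `slope`,
#'   `intercept`, `weighted_cor` and `degenerate`.
#' @export
calibration_curve <- function(y, p, bins = 10) {
  if (length(y) != length(p)) stop("'y' and 'p' must have equal length")
  if (length(y) < bins) stop("need at least 'bins' observations")
  id <- .prob_bins(p, bins)
  tab <- data.frame(
    n = as.vector(tapply(y, id, length)),
    mean_p = as.vector(tapply(p, id, mean)),
    obs_rate = as.vector(tapply(y, id, mean)))
  if (stats::sd(tab$mean_p) == 0 || nrow(tab) < 2L)
    return(list(table = tab, slope = NA_real_, intercept = NA_real_,
                weighted_cor = NA_real_, degenerate = TRUE))
  fit <- stats::lm(obs_rate ~ mean_p, data = tab, weights = tab$n)
  w <- tab$n / sum(tab$n)
  mx <- sum(w * tab$mean_p); my <- sum(w * tab$obs_rate)
  sxy <- sum(w * (tab$mean_p - mx) * (tab$obs_rate - my))
  sx <- sqrt(sum(w * (tab$mean_p - mx)^2))
  sy <- sqrt(sum(w * (tab$obs_rate - my)^2))
  list(table = tab,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       weighted_cor = if (sx > 0 && sy > 0) sxy / (sx * sy) else NA_real_,
       degenerate = FALSE)
}

#' Model-comparison battery for fitted ABTP models
#'
#' Computes, for each fitted model, the AUC with DeLong 95% CI, accuracy at
#' the 50% cutoff, AIC and delta-AIC against a designated baseline, Brier
#' score, Hosmer-Lemeshow p-value and the calibration slope, intercept and
#' weighted correlation — the standard comparison table for the four ABTP
#' curve families.
#'
#' @param fits Named list of fitted `"abtp"` models sharing the same data;
#'   names default to the model families.
#' @param baseline Baseline model name for delta-AIC (default `"lkb"` when
#'   present, else the first model, with a warning).
#' @param bins Probability bins for the HL test and calibration curve.
#' @return A data frame of class `"abtp_eval"`, one row per model, with
#'   attribute `"baseline"`.
#' @examples
#' herd <- generate_herd(herd_config(seed = 11))
#' d <- label_abnormal(herd)
#' fits <- lapply(c(lkb = "lkb", logistic = "logistic"),
#'                function(f) abtp(abnormal ~ thi, d, family = f))
#' evaluate_abtp(fits)
#' @export
evaluate_abtp <- function(fits, baseline = NULL, bins = 10) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "abtp")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$family, character(1))
  if (is.null(baseline)) {
    if ("lkb" %in% tolower(names(fits))) baseline <- "lkb"
    else {
      baseline <- names(fits)[1L]
      warning("no LKB model present; using '", baseline,
              "' as the delta-AIC baseline")
    }
  }
  y <- fits[[1L]]$data$y
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    p <- fitted(f)
    auc <- auc_with_ci(y, p)
    hl <- hosmer_lemeshow(y, p, bins = bins)
    cal <- calibration_curve(y, p, bins = bins)
    data.frame(model = nm,
               auc = auc[["auc"]], auc_ci_low = auc[["ci_low"]],
               auc_ci_high = auc[["ci_high"]],
               accuracy = accuracy_at(y, p),
               aic = stats::AIC(f),
               brier = brier_score(y, p),
               hl_p = hl$p_value,
               calibration_slope = cal$slope,
               calibration_intercept = cal$intercept,
               calibration_cor = cal$weighted_cor,
               tt50 = abtp_ttq(f, 0.5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_aic <- delta_aic(stats::setNames(out$aic, out$model),
                             baseline = baseline)
  out <- out[, c("model", "auc", "auc_ci_low", "auc_ci_high", "accuracy",
                 "aic", "delta_aic", "brier", "hl_p", "calibration_slope",
                 "calibration_intercept", "calibration_cor", "tt50")]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  class(out) <- c("abtp_eval", "data.frame")
  out
}

#' @export
print.abtp_eval <- function(x, digits = 3, ...) {
  d <- as.data.frame(x)
  d$auc <- sprintf("%.*f (%.*f-%.*f)", digits, d$auc, digits,
                   d$auc_ci_low, digits, d$auc_ci_high)
  d$auc_ci_low <- d$auc_ci_high <- NULL
  d$delta_aic <- ifelse(is.na(d$delta_aic), "-",
                        sprintf("%.2f", d$delta_aic))
  for (cl in c("accuracy", "aic", "brier", "hl_p", "calibration_slope",
               "calibration_intercept", "calibration_cor", "tt50"))
    d[[cl]] <- round(d[[cl]], digits)
  cat(sprintf("ABTP model evaluation (baseline for delta-AIC: %s)\n",
              attr(x, "baseline")))
  print(d, row.names = FALSE)
  invisible(x)
}
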