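#' Temperature-humidity index (THI)
#'
#' Computes the dairy-cattle THI from dry-bulb air temperature and relative
#' humidity:
#' `THI = (1.8 T + 32) - (0.55 - 0.0055 RH) (1.8 T - 26)`.
#' The index is dimensionless; at `RH = 100` the humidity correction vanishes
#' and THI reduces to the Fahrenheit temperature, and at `T = 26/1.8` degrees
#' Celsius the second factor is zero so THI is 58 regardless of humidity.
#'
#' @param temp Air temperature in degrees Celsius (vector).
#' @param humidity Relative humidity in percent, in `[0, 100]` (vector,
#'   recycled against `temp`).
#' @return THI values.
#' @examples
#' compute_thi(25, 100)            # 77
#' compute_thi(25.13, 83.79)       # herd-mean conditions, about 75.5
#' @export
compute_thi <- function(temp, humidity) {
  if (!is.numeric(temp) || !is.numeric(humidity))
    stop("'temp' and 'humidity' must be numeric")
  if (any(!is.finite(temp)) || any(!is.finite(humidity)))
    stop("non-finite temperature or humidity")
  if (any(humidity < 0 | humidity > 100))
    stop("'humidity' must lie in [0, 100] percent")
  (1.8 * temp + 32) - (0.55 - 0.0055 * humidity) * (1.8 * temp - 26)
}

#' Abnormal-temperature labelling rule
#'
#' Defines how the binary abnormal-body-temperature outcome is derived from
#' eye-socket temperatures.  With `reference = "annual_mean"` (default) an
#' animal is abnormal when its temperature strictly exceeds the dataset mean
#' plus `offset`; with `"fixed_threshold"` the comparison is against
#' `fixed_value`.  The one-sided upward rule reflects that heat stress
#' elevates body temperature.
#'
#' @param reference `"annual_mean"` or `"fixed_threshold"`.
#' @param offset Degrees Celsius added to the annual mean (default 0).
#' @param fixed_value Threshold in degrees Celsius used with
#'   `"fixed_threshold"` (default 38.32, the critical body temperature).
#' @return An object of class `"label_rule"`.
#' @export
label_rule <- function(reference = c("annual_mean", "fixed_threshold"),
                       offset = 0, fixed_value = 38.32) {
  reference <- match.arg(reference)
  if (!is.finite(offset)) stop("'offset' must be finite")
  if (reference == "fixed_threshold" &&
      (!is.finite(fixed_value) || fixed_value <= 0))
    stop("'fixed_value' must be a positive temperature")
  structure(list(reference = reference, offset = offset,
                 fixed_value = fixed_value), class = "label_rule")
}

# canonical feature columns of a labelled dataset, in model order
.abtp_features <- c("thi", "temperature", "humidity", "age", "days_in_milk",
                    "parity", "body_weight", "milk_yield")

#' Label abnormal body temperatures and assemble the modelling dataset
#'
#' Computes THI from ambient temperature and humidity, applies the labelling
#' rule to the eye-socket temperatures and returns the feature matrix used by
#' the LASSO ranking and ABTP fits: `thi`, `temperature`, `humidity`, `age`,
#' `days_in_milk`, `parity`, `body_weight`, `milk_yield` plus the binary
#' `abnormal` outcome and the `eye_temp` it was derived from.
#'
#' @param records Herd data frame with the [generate_herd()] /
#'   [read_herd_csv()] schema.
#' @param rule A [label_rule()]; default: strictly above the dataset mean.
#' @return A data frame with attributes `threshold` (the cutoff actually
#'   used, in degrees Celsius) and `rule`.
#' @examples
#' herd <- generate_herd(herd_config(n_animals = 50, seed = 1))
#' d <- label_abnormal(herd)
#' table(d$abnormal)
#' @export
label_abnormal <- function(records, rule = label_rule()) {
  stopifnot(inherits(rule, "label_rule"))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame")
  need <- c("eye_temp", "ambient_temp", "humidity", "age", "days_in_milk",
            "parity", "body_weight", "milk_yield")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$eye_temp)))
    stop("non-finite eye-socket temperatures")
  threshold <- switch(rule$reference,
    annual_mean = mean(records$eye_temp) + rule$offset,
    fixed_threshold = rule$fixed_value)
  out <- data.frame(
    thi = compute_thi(records$ambient_temp, records$humidity),
    temperature = records$ambient_temp,
    humidity = records$humidity,
    age = records$age,
    days_in_milk = records$days_in_milk,
    parity = records$parity,
    body_weight = records$body_weight,
    milk_yield = records$milk_yield,
    eye_temp = records$eye_temp,
    abnormal = as.integer(records$eye_temp > threshold))
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- rule
  out
}

#' Body-temperature triage bands
#'
#' Constructs the three-band triage scheme: temperatures below `normal_below`
#' are normal, temperatures from `normal_below` up to (but excluding)
#' `observe_upper` warrant observation, and temperatures at or above
#' `observe_upper` are abnormal and require immediate notification.
#' `observe_upper` is derived as `round(normal_below * (1 + instrument_margin),
#' 2)` — the critical temperature inflated by the thermal imager's relative
#' accuracy margin; with the defaults, `round(38.32 * 1.02, 2) = 39.09`.
#'
#' @param normal_below Critical body temperature in degrees Celsius
#'   (default 38.32).
#' @param instrument_margin Relative instrument accuracy (default 0.02).
#' @param thi_alert THI above which an environmental heat-stress alert is
#'   issued (default 75).
#' @return An object of class `"triage_bands"` with fields `normal_below`,
#'   `observe_upper`, `instrument_margin`, `thi_alert`.
#' @examples
#' triage_bands()$observe_upper   # 39.09
#' @export
triage_bands <- function(normal_below = 38.32, instrument_margin = 0.02,
                         thi_alert = 75) {
  if (!is.finite(normal_below) || normal_below <= 0)
    stop("'normal_below' must be a positive temperature")
  if (!is.finite(instrument_margin) || instrument_margin < 0)
    stop("'instrument_margin' must be non-negative")
  if (!is.finite(thi_alert) || thi_alert <= 0)
    stop("'thi_alert' must be positive")
  observe_upper <- round(normal_below * (1 + instrument_margin), 2)
  if (!(normal_below < observe_upper))
    stop("'instrument_margin' too small: bands collapse")
  structure(list(normal_below = normal_below, observe_upper = observe_upper,
                 instrument_margin = instrument_margin,
                 thi_alert = thi_alert), class = "triage_bands")
}

#' @export
print.triage_bands <- function(x, ...) {
  cat(sprintf(paste0("Triage bands: normal < %.2f degC <= observe < %.2f ",
                     "degC <= abnormal; THI alert > %.1f\n"),
              x$normal_below, x$observe_upper, x$thi_alert))
  invisible(x)
}

#' Classify body temperatures into triage bands
#'
#' @param temp Body temperatures in degrees Celsius (vector).
#' @param bands A [triage_bands()] object.
#' @return Factor with levels `normal`, `observe`, `abnormal`; every finite
#'   temperature falls in exactly one band.
#' @examples
#' classify_temperature(c(38.00, 38.32, 39.09, 39.50), triage_bands())
#' @export
classify_temperature <- function(temp, bands = triage_bands()) {
  stopifnot(inherits(bands, "triage_bands"))
  if (any(!is.finite(temp))) stop("non-finite temperature")
  out <- ifelse(temp < bands$normal_below, "normal",
         ifelse(temp < bands$observe_upper, "observe", "abnormal"))
  factor(out, levels = c("normal", "observe", "abnormal"))
}

#' Environmental THI alert
#'
#' `TRUE` when the THI strictly exceeds the alert level of the band scheme
#' (default 75), signalling environmental heat stress.
#'
#' @param thi THI values (vector).
#' @param bands A [triage_bands()] object.
#' @return Logical vector.
#' @examples
#' thi_alert(c(75, 75.01))   # FALSE TRUE
#' @export
thi_alert <- function(thi, bands = triage_bands()) {
  stopifnot(inherits(bands, "triage_bands"))
  if (any(!is.finite(thi))) stop("non-finite THI")
  thi > bands$thi_alert
}
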