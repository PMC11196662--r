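#' Synthetic herd configuration
#'
#' Parameters of the synthetic dairy-herd generator.  Defaults reproduce the
#' published summary statistics of the 320-animal Holstein-Friesian study
#' herd: eye-socket temperature 38.3 +/- 1.40 degC, air temperature 25.13 +/-
#' 4.55 degC, relative humidity 83.79 +/- 7.90 %, age 49 +/- 27 months, days
#' in milk 194 +/- 132, parity 2 +/- 1, body weight 599.76 +/- 81.07 kg,
#' milk yield 22.27 +/- 6.87 l.  THI is not drawn: it is computed from the
#' generated temperature and humidity, whose bivariate-Gaussian correlation
#' defaults to -0.3 (diurnal anticorrelation); the implied THI distribution
#' lands close to the published 75.37 +/- 7.11.
#'
#' Eye-socket temperature follows one of two mechanisms.  Under
#' `"temperature_generative"` (default) it is a piecewise-linear "knee"
#' response to THI: `baseline + response_slope * max(0, THI - response_knee) +
#' N(0, noise_sd)` with baseline 38.1 degC and knee at THI 70, above which
#' orbital temperatures rise sharply.  The default slope (0.032 degC per THI
#' unit) and noise SD (1.39 degC) are calibrated so the marginal eye-socket
#' moments match 38.3 +/- 1.40.  Under `"bernoulli_direct"` eye temperatures
#' are drawn independently and abnormality labels are instead meant to be
#' simulated from a known ABTP ground truth via [simulate_abtp_labels()].
#'
#' @param n_animals Number of animals (>= 1), default 320.
#' @param ambient_temp_mean,ambient_temp_sd Air temperature moments (degC).
#' @param humidity_mean,humidity_sd Relative humidity moments (%); draws are
#'   truncated to `[0, 100]`.
#' @param age_mean,age_sd Age moments (months); truncated at 0, integer.
#' @param days_in_milk_mean,days_in_milk_sd Days in milk; truncated at 0,
#'   integer.
#' @param parity_mean,parity_sd Parity (calvings); truncated at 0, integer.
#' @param body_weight_mean,body_weight_sd Body weight (kg), truncated at 0.
#' @param milk_yield_mean,milk_yield_sd Milk yield (l), truncated at 0.
#' @param eye_temp_mean,eye_temp_sd Eye-socket temperature moments (degC);
#'   used directly under `"bernoulli_direct"` and as the calibration target
#'   of the generative mechanism.
#' @param temp_rh_correlation Temperature/humidity correlation in `[-1, 1]`.
#' @param label_mechanism `"temperature_generative"` or `"bernoulli_direct"`.
#' @param ground_truth Optional [abtp_params()] ground truth for
#'   `"bernoulli_direct"`.
#' @param baseline_eye_temp Baseline eye-socket temperature (degC).
#' @param response_knee THI where eye temperature starts rising.
#' @param response_slope degC per THI unit above the knee.
#' @param noise_sd Gaussian measurement/biological noise SD (degC).
#' @param seed Optional integer seed; a fixed seed makes [generate_herd()]
#'   fully reproducible.
#' @return An object of class `"herd_config"`.
#' @export
herd_config <- function(n_animals = 320,
                        ambient_temp_mean = 25.13, ambient_temp_sd = 4.55,
                        humidity_mean = 83.79, humidity_sd = 7.90,
                        age_mean = 49, age_sd = 27,
                        days_in_milk_mean = 194, days_in_milk_sd = 132,
                        parity_mean = 2, parity_sd = 1,
                        body_weight_mean = 599.76, body_weight_sd = 81.07,
                        milk_yield_mean = 22.27, milk_yield_sd = 6.87,
                        eye_temp_mean = 38.3, eye_temp_sd = 1.40,
                        temp_rh_correlation = -0.3,
                        label_mechanism = c("temperature_generative",
                                            "bernoulli_direct"),
                        ground_truth = NULL,
                        baseline_eye_temp = 38.1,
                        response_knee = 70,
                        response_slope = 0.032,
                        noise_sd = 1.39,
                        seed = NULL) {
  label_mechanism <- match.arg(label_mechanism)
  cfg <- list(n_animals = n_animals,
              ambient_temp_mean = ambient_temp_mean,
              ambient_temp_sd = ambient_temp_sd,
              humidity_mean = humidity_mean, humidity_sd = humidity_sd,
              age_mean = age_mean, age_sd = age_sd,
              days_in_milk_mean = days_in_milk_mean,
              days_in_milk_sd = days_in_milk_sd,
              parity_mean = parity_mean, parity_sd = parity_sd,
              body_weight_mean = body_weight_mean,
              body_weight_sd = body_weight_sd,
              milk_yield_mean = milk_yield_mean,
              milk_yield_sd = milk_yield_sd,
              eye_temp_mean = eye_temp_mean, eye_temp_sd = eye_temp_sd,
              temp_rh_correlation = temp_rh_correlation,
              label_mechanism = label_mechanism,
              ground_truth = ground_truth,
              baseline_eye_temp = baseline_eye_temp,
              response_knee = response_knee,
              response_slope = response_slope,
              noise_sd = noise_sd, seed = seed)
  if (!is.numeric(n_animals) || length(n_animals) != 1L || n_animals < 1)
    stop("'n_animals' must be a positive count")
  cfg$n_animals <- as.integer(n_animals)
  sds <- grep("_sd$", names(cfg), value = TRUE)
  if (any(vapply(cfg[sds], function(s) !is.finite(s) || s < 0, logical(1))))
    stop("all standard deviations must be finite and >= 0")
  if (!is.finite(temp_rh_correlation) || abs(temp_rh_correlation) > 1)
    stop("'temp_rh_correlation' must lie in [-1, 1]")
  if (!is.null(ground_truth) && !inherits(ground_truth, "abtp_params"))
    stop("'ground_truth' must be an abtp_params object")
  structure(cfg, class = "herd_config")
}

#' Generate a synthetic dairy herd
#'
#' Draws `n_animals` per-animal records under a [herd_config()].  Air
#' temperature and relative humidity come from a bivariate Gaussian with the
#' configured correlation (humidity truncated to `[0, 100]`); age, days in
#' milk and parity are truncated at 0 and rounded to integers; weight and
#' yield are truncated at 0.  Eye-socket temperature follows the configured
#' mechanism (see [herd_config()]).  An identical seed yields an identical
#' data set across sessions.
#'
#' @param config A [herd_config()].
#' @return Data frame with columns `animal_id`, `eye_temp`, `ambient_temp`,
#'   `humidity`, `age`, `days_in_milk`, `parity`, `body_weight`,
#'   `milk_yield`, with the config attached as attribute `"config"`.
#' @examples
#' herd <- generate_herd(herd_config(n_animals = 10, seed = 7))
#' head(herd)
#' @export
generate_herd <- function(config = herd_config()) {
  stopifnot(inherits(config, "herd_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_animals
  rho <- config$temp_rh_correlation

  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  ambient_temp <- config$ambient_temp_mean + config$ambient_temp_sd * z1
  humidity <- pmin(pmax(config$humidity_mean + config$humidity_sd * z2,
                        0), 100)

  age <- round(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 0))
  dim_ <- round(pmax(stats::rnorm(n, config$days_in_milk_mean,
                                  config$days_in_milk_sd), 0))
  parity <- round(pmax(stats::rnorm(n, config$parity_mean,
                                    config$parity_sd), 0))
  body_weight <- pmax(stats::rnorm(n, config$body_weight_mean,
                                   config$body_weight_sd), 0)
  milk_yield <- pmax(stats::rnorm(n, config$milk_yield_mean,
                                  config$milk_yield_sd), 0)

  if (config$label_mechanism == "temperature_generative") {
    thi <- compute_thi(ambient_temp, humidity)
    eye_temp <- config$baseline_eye_temp +
      config$response_slope * pmax(0, thi - config$response_knee) +
      stats::rnorm(n, 0, config$noise_sd)
  } else {
    eye_temp <- stats::rnorm(n, config$eye_temp_mean, config$eye_temp_sd)
  }

  out <- data.frame(
    animal_id = sprintf("cow_%05d", seq_len(n)),
    eye_temp = eye_temp,
    ambient_temp = ambient_temp,
    humidity = humidity,
    age = age,
    days_in_milk = dim_,
    parity = parity,
    body_weight = body_weight,
    milk_yield = milk_yield,
    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Simulate abnormality labels directly from an ABTP ground truth
#'
#' Draws independent Bernoulli outcomes with success probability given by an
#' ABTP curve evaluated at the supplied risk-factor values.  This is the
#' `"bernoulli_direct"` labelling mechanism, used for parameter-recovery
#' experiments where the generating curve is known.
#'
#' @param thi Risk-factor values (e.g. THI).
#' @param params An [abtp_params()] ground truth.
#' @param seed Optional integer seed.
#' @return Integer 0/1 vector, same length as `thi`.
#' @examples
#' p <- abtp_params("logistic", beta0 = -22.5, beta1 = 0.30)
#' mean(simulate_abtp_labels(rep(75, 1000), p, seed = 1))  # about 0.5
#' @export
simulate_abtp_labels <- function(thi, params, seed = NULL) {
  stopifnot(inherits(params, "abtp_params"))
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(length(thi), 1L, abtp_prob(params, thi))
}

# herd CSV schema, in order
.herd_columns <- c("animal_id", "eye_temp", "ambient_temp", "humidity",
                   "age", "days_in_milk", "parity", "body_weight",
                   "milk_yield")

#' Write a herd data set to CSV
#'
#' Writes the documented herd schema (`animal_id`, `eye_temp`,
#' `ambient_temp`, `humidity`, `age`, `days_in_milk`, `parity`,
#' `body_weight`, `milk_yield`), one row per animal, with numeric fields at
#' full double precision (17 significant digits) so that a write/read
#' round-trip is lossless.
#'
#' @param records Herd data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_herd_csv <- function(records, path) {
  miss <- setdiff(.herd_columns, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- records[.herd_columns]
  for (cl in .herd_columns[-1L])
    out[[cl]] <- sprintf("%.17g", records[[cl]])
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a herd data set from CSV
#'
#' Validates the documented schema: missing columns, unparseable numeric
#' fields and humidity outside `[0, 100]` are reported with the offending
#' column and row numbers.  Unknown extra columns are preserved in the
#' `"extra_columns"` attribute with a warning.
#'
#' @param path CSV file path.
#' @return Herd data frame in schema column order.
#' @export
read_herd_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.herd_columns, names(raw))
  if (length(miss))
    stop("herd CSV is missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(animal_id = raw$animal_id, stringsAsFactors = FALSE)
  for (cl in .herd_columns[-1L]) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad))
      stop(sprintf("column '%s': unparseable numeric value at row(s) %s",
                   cl, paste(utils::head(bad, 5), collapse = ", ")))
    out[[cl]] <- v
  }
  bad_rh <- which(out$humidity < 0 | out$humidity > 100)
  if (length(bad_rh))
    stop("humidity outside [0, 100] at row(s) ",
         paste(utils::head(bad_rh, 5), collapse = ", "))
  extra <- setdiff(names(raw), .herd_columns)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    attr(out, "extra_columns") <- raw[extra]
  }
  out
}
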