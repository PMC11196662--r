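test_that("AUC matches exhaustive pair enumeration, including ties", {
  expect_equal(auc_with_ci(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))[["auc"]], 1)
  expect_equal(auc_with_ci(c(0, 1), c(0.5, 0.5))[["auc"]], 0.5)
  # five-point instance, enumerated by hand over the 6 pos-neg pairs
  y5 <- c(0, 1, 0, 1, 1); p5 <- c(0.2, 0.3, 0.4, 0.6, 0.1)
  expect_equal(auc_with_ci(y5, p5)[["auc"]], auc_bruteforce(y5, p5))
  set.seed(50)
  for (i in 1:15) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4); if (length(unique(y)) < 2) y[1:2] <- 0:1
    p <- round(runif(n), 2)               # rounding forces ties
    got <- auc_with_ci(y, p)
    expect_equal(got[["auc"]], auc_bruteforce(y, p), tolerance = 1e-12)
    expect_true(got[["ci_low"]] <= got[["auc"]] &&
                  got[["auc"]] <= got[["ci_high"]])
  }
  expect_error(auc_with_ci(rep(1, 5), runif(5)), "both")
})

test_that("accuracy uses the strict exceeds-threshold convention", {
  expect_equal(accuracy_at(c(0, 1, 1), c(0, 1, 1)), 1)
  y <- c(1, 1, 0, 0, 1)
  expect_equal(accuracy_at(y, rep(0.5, 5)), 1 - mean(y))  # all predicted 0
  expect_equal(accuracy_at(c(1, 0, 1, 0), c(0.6, 0.6, 0.4, 0.4)), 0.5)
})

test_that("delta-AIC arithmetic and invariances hold", {
  aics <- c(LKB = 361.28, Logistic = 361.60, Schultheiss = 361.56,
            Poisson = 362.22)
  d <- delta_aic(aics)
  expect_true(is.na(d[["LKB"]]))
  expect_equal(unname(d[-1]), c(0.32, 0.28, 0.94))
  expect_equal(unname(delta_aic(c(a = 3, LKB = 3, b = 3))), c(0, NA, 0))
  expect_true(all(delta_aic(aics)[-1] >= 0))   # baseline is the minimum
  # adding a constant to every log-likelihood shifts all AICs equally
  expect_equal(delta_aic(aics + 12.34)[-1], d[-1])
  expect_error(delta_aic(aics, baseline = "Weibull"), "not found")
})

test_that("Brier score matches arithmetic and its decomposition identity", {
  set.seed(51)
  y <- rbinom(40, 1, 0.3)
  expect_equal(brier_score(y, rep(0.5, 40)), 0.25)
  expect_equal(brier_score(y, y), 0)
  expect_equal(brier_score(c(1, 0), c(0.8, 0.4)), 0.10)
  expect_equal(brier_score(y, rep(mean(y), 40)), mean(y) * (1 - mean(y)),
               tolerance = 1e-12)
})

test_that("HL test accepts calibrated forecasts and rejects miscalibrated", {
  ok_null <- 0L; ok_power <- 0L
  for (r in 1:100) {
    set.seed(600 + r)
    p <- runif(1000, 0.05, 0.95)
    y <- rbinom(1000, 1, p)
    if (hosmer_lemeshow(y, p)$p_value > 0.05) ok_null <- ok_null + 1L
    set.seed(600 + r)
    p2 <- runif(5000, 0.05, 0.95)
    y2 <- rbinom(5000, 1, p2)
    if (hosmer_lemeshow(y2, p2^2)$p_value < 0.05) ok_power <- ok_power + 1L
  }
  expect_gte(ok_null, 90L)
  expect_gte(ok_power, 90L)
})

test_that("HL degrees of freedom and degenerate bins are guarded", {
  set.seed(52)
  p <- runif(100, 0.2, 0.8); y <- rbinom(100, 1, p)
  hl <- hosmer_lemeshow(y, p, bins = 10)
  expect_equal(hl$df, 8L)
  expect_equal(sum(hl$table$n), 100)
  expect_error(hosmer_lemeshow(y, p, bins = 2), "degrees of freedom")
  # an all-zero-probability group gets merged, not divided by zero
  p0 <- c(rep(0, 20), runif(80, 0.3, 0.7))
  y0 <- c(rep(0, 20), rbinom(80, 1, p0[21:100]))
  expect_message(hl0 <- hosmer_lemeshow(y0, p0, bins = 10), "merging")
  expect_true(is.finite(hl0$statistic))
})

test_that("HL bin assignment is invariant to monotone rescaling", {
  set.seed(53)
  p <- runif(500); y <- rbinom(500, 1, p)
  a <- hosmer_lemeshow(y, p)$table
  b <- hosmer_lemeshow(y, sqrt(p))$table      # same order, same members
  expect_equal(a$n, b$n)
  expect_equal(a$observed, b$observed)
})

test_that("calibration slope is near 1 for calibrated forecasts", {
  set.seed(54)
  p <- runif(20000, 0.02, 0.98)
  y <- rbinom(20000, 1, p)
  cal <- calibration_curve(y, p)
  expect_false(cal$degenerate)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_gt(cal$intercept, -0.05); expect_lt(cal$intercept, 0.05)
  expect_gt(cal$weighted_cor, 0.95)
})

test_that("calibration degenerates gracefully and finds null slopes", {
  set.seed(55)
  y <- rbinom(200, 1, 0.4)
  cal <- calibration_curve(y, rep(mean(y), 200))
  expect_true(cal$degenerate)
  expect_true(is.na(cal$slope))
  p <- runif(10000); y2 <- rbinom(10000, 1, 0.5)   # independent of p
  expect_lt(abs(calibration_curve(y2, p)$slope), 0.1)
})

test_that("the evaluation battery produces a coherent comparison table", {
  herd <- generate_herd(herd_config(seed = 60))
  d <- label_abnormal(herd)
  d$abnormal <- simulate_abtp_labels(
    d$thi, abtp_params("logistic", beta0 = -22.5, beta1 = 0.30), seed = 61)
  fits <- lapply(stats::setNames(nm = abtp_families),
                 function(f) abtp(abnormal ~ thi, d, family = f))
  rep_ <- evaluate_abtp(fits)
  expect_s3_class(rep_, "abtp_eval")
  expect_equal(nrow(rep_), 4L)
  expect_true(is.na(rep_$delta_aic[rep_$model == "lkb"]))
  expect_true(all(rep_$auc >= 0 & rep_$auc <= 1))
  expect_true(all(rep_$brier >= 0 & rep_$brier <= 1))
  expect_equal(rep_$delta_aic[-1],
               rep_$aic[-1] - rep_$aic[1], tolerance = 1e-12)
  expect_output(print(rep_), "baseline")
  # single-model report falls back with a warning when LKB is absent
  expect_warning(r1 <- evaluate_abtp(fits["logistic"]), "baseline")
  expect_equal(nrow(r1), 1L)
})
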