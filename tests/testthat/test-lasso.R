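# orthonormal design with X'X = n I, so the penalised solution has the
# analytic soft-threshold form
make_orthonormal <- function(n = 50, k = 3, seed = 2) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * k), n, k))) * sqrt(n)
  colnames(q) <- paste0("f", seq_len(k))
  q
}

test_that("path equals analytic soft-thresholding on orthonormal designs", {
  x <- make_orthonormal()
  set.seed(3)
  beta_true <- c(1.5, -0.8, 0.1)
  y <- drop(x %*% beta_true) + rnorm(50, sd = 0.3)
  bhat <- drop(crossprod(x, y)) / 50          # unpenalised estimates
  for (lam in c(0.05, 0.3, 1)) {
    path <- fit_lasso_path(list(x = x, y = y), family = "gaussian",
                           lambda = lam, standardize = FALSE,
                           intercept = FALSE)
    expect_equal(drop(path$beta),
                 sign(bhat) * pmax(abs(bhat) - lam, 0),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the largest path penalty shrinks every coefficient to zero", {
  d <- label_abnormal(generate_herd(herd_config(seed = 4)))
  path <- fit_lasso_path(d)
  expect_true(all(abs(path$beta[, 1]) < 1e-10))
  expect_true(any(abs(path$beta[, ncol(path$beta)]) > 0))
})

test_that("duplicated features split the coefficient of the original", {
  x <- make_orthonormal(n = 200, k = 3, seed = 5)
  set.seed(6)
  y <- drop(x %*% c(1.2, -0.6, 0.4)) + rnorm(200, sd = 0.2)
  lam <- 0.1
  base <- fit_lasso_path(list(x = x, y = y), family = "gaussian",
                         lambda = lam, standardize = FALSE,
                         intercept = FALSE)
  xdup <- cbind(x, f1b = x[, 1])
  dup <- fit_lasso_path(list(x = xdup, y = y), family = "gaussian",
                        lambda = lam, standardize = FALSE,
                        intercept = FALSE)
  expect_equal(dup$beta["f1", 1] + dup$beta["f1b", 1],
               base$beta["f1", 1], tolerance = 1e-3)
  expect_equal(dup$beta["f2", 1], base$beta["f2", 1], tolerance = 1e-3)
})

test_that("a THI-driven outcome puts THI first in the ranking", {
  # THI alone drives the labels; the other seven factors are reduced to
  # independent noise (marginals kept, joint dependence destroyed by
  # permutation) so that importance is attributable
  gt <- abtp_params("logistic", beta0 = -22.5, beta1 = 0.30)
  others <- c("temperature", "humidity", "age", "days_in_milk",
              "parity", "body_weight", "milk_yield")
  hits <- 0L
  for (r in 1:20) {
    herd <- generate_herd(herd_config(seed = 300 + r))
    d <- label_abnormal(herd)
    set.seed(5000 + r)
    for (cl in others) d[[cl]] <- sample(d[[cl]])
    d$abnormal <- simulate_abtp_labels(d$thi, gt)
    hits <- hits + (rank_factors(fit_lasso_path(d))[1] == "thi")
  }
  expect_gte(hits, 19L)
})

test_that("pure-noise outcomes rank without crashing and select ~0 coefs", {
  herd <- generate_herd(herd_config(seed = 40))
  d <- label_abnormal(herd)
  set.seed(41)
  d$abnormal <- rbinom(nrow(d), 1, 0.5)     # independent of every feature
  path <- fit_lasso_path(d)
  path$selected_lambda <- select_lambda_cv(d, seed = 41)
  expect_setequal(rank_factors(path),
                  c("thi", "temperature", "humidity", "age", "days_in_milk",
                    "parity", "body_weight", "milk_yield"))
  j <- which.min(abs(path$lambda - path$selected_lambda))
  expect_true(all(abs(path$beta[, j]) < 0.25))
})

test_that("exact ties are broken by column order", {
  set.seed(42)
  x <- matrix(rnorm(200 * 2), 200, 2)
  x <- cbind(a = x[, 1], b = x[, 1], c = x[, 2])   # a and b identical
  y <- rbinom(200, 1, plogis(x[, 1] + 0.5 * x[, 3]))
  path <- fit_lasso_path(list(x = x, y = y), family = "binomial",
                         standardize = FALSE)
  rk <- rank_factors(path)
  expect_lt(match("a", rk), match("b", rk))
})

test_that("ranking is invariant to the scale of a raw feature", {
  herd <- generate_herd(herd_config(seed = 43))
  d <- label_abnormal(herd)
  r1 <- rank_factors(fit_lasso_path(d))
  d2 <- d; d2$body_weight <- d2$body_weight * 1000
  r2 <- rank_factors(fit_lasso_path(d2))
  expect_identical(r1, r2)
})

test_that("constant feature columns are dropped with a warning", {
  herd <- generate_herd(herd_config(seed = 44))
  d <- label_abnormal(herd)
  d$parity <- 2
  expect_warning(path <- fit_lasso_path(d), "parity")
  expect_identical(path$dropped, "parity")
  expect_identical(rank_factors(path)[8], "parity")  # demoted to last
})

test_that("cross-validated penalty keeps a strong single driver", {
  gt <- abtp_params("logistic", beta0 = -45, beta1 = 0.60)  # steep in THI
  herd <- generate_herd(herd_config(n_animals = 600, seed = 45))
  d <- label_abnormal(herd)
  set.seed(46)   # decouple the driver from its collinear companions
  for (cl in c("temperature", "humidity", "age", "days_in_milk",
               "parity", "body_weight", "milk_yield"))
    d[[cl]] <- sample(d[[cl]])
  d$abnormal <- simulate_abtp_labels(d$thi, gt, seed = 45)
  lam <- select_lambda_cv(d, folds = 10, seed = 45)
  path <- fit_lasso_path(d)
  j <- which.min(abs(path$lambda - lam))
  expect_gt(abs(path$beta["thi", j]), 0)
  # fold count does not change the retained top factor
  lam2 <- select_lambda_cv(d, folds = 2, seed = 45)
  path$selected_lambda <- lam2
  expect_identical(rank_factors(path)[1], "thi")
  expect_identical(select_lambda_cv(d, folds = 10, seed = 45), lam)
  expect_error(select_lambda_cv(d, folds = 1), ">= 2")
})

test_that("near-random labels push the CV penalty toward the null end", {
  herd <- generate_herd(herd_config(seed = 46))
  d <- label_abnormal(herd)
  set.seed(46)
  d$abnormal <- rbinom(nrow(d), 1, 0.5)
  lam <- select_lambda_cv(d, seed = 46)
  path <- fit_lasso_path(d)
  # selected penalty sits in the upper (strong-shrinkage) half of the grid
  expect_gte(lam, sort(path$lambda)[length(path$lambda) %/% 2])
})
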