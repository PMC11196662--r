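# frozen ground truth used for recovery checks (see the methods vignette
# for the design rationale)
eff_truth <- function() {
  eff_index_model(tn50_at_unit = 75 * 38.3^0.8, c = 0.8, m = 0.04,
                  n_ref = 75)
}

simulate_eff <- function(model, n = 5000, seed = 1) {
  set.seed(seed)
  d <- data.frame(thi = runif(n, 55, 95), temp = runif(n, 33, 45))
  teff <- effective_temperature(d$temp, d$thi, model)
  d$abnormal <- rbinom(n, 1, lkb_eff_prob(teff, model))
  d
}

test_that("power-law threshold evaluates exactly", {
  m <- eff_index_model(100, c = 0.08, m = 0.05, n_ref = 75)
  expect_equal(tn50_power_law(1, m), 100)          # unit temperature
  expect_equal(tn50_power_law(38.32, m), 74.7009216245, tolerance = 1e-9)
  m0 <- eff_index_model(100, c = 0, m = 0.05, n_ref = 75)
  expect_equal(tn50_power_law(c(1, 20, 40), m0), rep(100, 3))
  expect_error(tn50_power_law(-3, m), "positive")
})

test_that("effective temperature is the identity at the reference factor", {
  set.seed(20)
  for (i in 1:20) {
    m <- eff_index_model(runif(1, 50, 200), c = runif(1, 0.01, 1),
                         m = runif(1, 0.01, 0.5), n_ref = runif(1, 60, 90))
    t_i <- runif(1, 36, 41)
    expect_identical(effective_temperature(t_i, m$n_ref, m), t_i)
  }
  m <- eff_index_model(100, c = 0, m = 0.05, n_ref = 75)
  expect_equal(effective_temperature(38.3, c(10, 75, 200), m), rep(38.3, 3))
  m2 <- eff_index_model(100, c = 0.1, m = 0.05, n_ref = 75)
  expect_equal(effective_temperature(38.3, 150, m2), 38.3 * 2^(-0.1),
               tolerance = 1e-12)
  expect_error(effective_temperature(38.3, -1, m2), "positive")
})

test_that("probit surface matches chained hand arithmetic", {
  m <- eff_index_model(100, c = 0.08, m = 0.05, n_ref = 75)
  t50e <- 100 * 38.32^(-0.08)
  u <- (75 - t50e) / (0.05 * t50e)
  expect_equal(lkb_eff_prob(38.32, m), pnorm(u), tolerance = 1e-12)
  expect_equal(lkb_eff_prob(38.32, m), 0.531910617872, tolerance = 1e-9)
  # a flat slope pulls every probability toward 1/2
  mflat <- eff_index_model(100, c = 0.08, m = 100, n_ref = 75)
  expect_lt(abs(lkb_eff_prob(38.32, mflat) - 0.5), 1e-3)
  # the 50% point: temp_eff where tn50_at_unit * temp^-c = n_ref
  t_half <- (100 / 75)^(1 / 0.08)
  expect_equal(lkb_eff_prob(t_half, m), 0.5, tolerance = 1e-10)
  expect_error(lkb_eff_prob(-1, m), "positive")
})

test_that("surface is non-decreasing in effective temperature when c > 0", {
  m <- eff_truth()
  te <- seq(33, 45, length.out = 300)
  expect_true(all(diff(lkb_eff_prob(te, m)) >= 0))
})

test_that("joint MLE recovers the generating parameters", {
  truth <- eff_truth()
  target <- coef_truth <- c(truth$tn50_at_unit, truth$c, truth$m)
  ok <- 0L
  for (r in 1:3) {
    d <- simulate_eff(truth, n = 5000, seed = 400 + r)
    fit <- abtp_eff(abnormal ~ thi + temp, d, n_ref = 75)
    rel <- abs(coef(fit) - target) / target
    if (all(rel < 0.10)) ok <- ok + 1L
    expect_true(fit$converged)
  }
  expect_gte(ok, 2L)
})

test_that("refitting the effective-index model is deterministic", {
  d <- simulate_eff(eff_truth(), n = 800, seed = 77)
  f1 <- abtp_eff(abnormal ~ thi + temp, d, n_ref = 75)
  f2 <- abtp_eff(abnormal ~ thi + temp, d, n_ref = 75)
  expect_identical(coef(f1), coef(f2))
})

test_that("iso-contours satisfy their defining equation to 1e-6", {
  # exponents chosen so both probability levels are reachable inside the
  # search bracket for either numerator convention
  models <- list(
    reference = eff_index_model(75 * 38.3^0.8, c = 0.8, m = 0.04,
                                n_ref = 75, numerator = "reference"),
    observed = eff_index_model(75 * 38.3^0.3, c = 0.3, m = 0.1,
                               n_ref = 75, numerator = "observed"))
  for (m in models) {
    for (q in c(0.2, 0.5)) {
      con <- iso_probability_contour(m, q, temp_grid = seq(36, 41, 0.25))
      expect_true(all(con$ok))
      probs <- vapply(seq_len(nrow(con)), function(i)
        abtp:::.eff_surface_prob(con$thi[i], con$temp[i], m), numeric(1))
      expect_equal(probs, rep(q, nrow(con)), tolerance = 1e-6)
    }
  }
})

test_that("under the monotone surface the 20% contour sits below the 50%", {
  m <- eff_index_model(75 * 38.3^0.3, c = 0.3, m = 0.1, n_ref = 75,
                       numerator = "observed")
  g <- seq(36, 41, 0.1)
  c20 <- iso_probability_contour(m, 0.2, g)
  c50 <- iso_probability_contour(m, 0.5, g)
  expect_true(all(c20$thi < c50$thi))        # contours never cross
})

test_that("c = 0 decouples the factor: contours are vertical lines", {
  m <- eff_index_model(75, c = 0, m = 0.1, n_ref = 75,
                       numerator = "observed")
  con <- iso_probability_contour(m, 0.5, seq(36, 41, 0.5))
  expect_equal(diff(range(con$thi)), 0, tolerance = 1e-6)
  expect_equal(con$thi[1], 75, tolerance = 1e-6)
})

test_that("unreachable contour levels are reported per grid point", {
  m <- eff_index_model(75, c = 0, m = 0.1, n_ref = 75)  # flat in THI
  con <- iso_probability_contour(m, 0.9, seq(36, 41, 1))
  expect_true(all(!con$ok))
  expect_true(all(is.na(con$thi)))
})

test_that("effective-index fit validates its inputs", {
  d <- simulate_eff(eff_truth(), n = 100, seed = 9)
  d$abnormal <- 0L
  expect_error(abtp_eff(abnormal ~ thi + temp, d), "both outcome classes")
  expect_error(abtp_eff(abnormal ~ thi, d), "body_temperature")
})
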