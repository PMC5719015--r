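test_that("logit and inverse logit are exact, stable and inverse", {
  expect_equal(logit(0.5), 0)
  expect_equal(inv_logit(0), 0.5)
  expect_equal(round(inv_logit(2.7006), 4), 0.9371)
  expect_equal(logit(inv_logit(2.7006)), 2.7006, tolerance = 1e-12)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(inv_logit(logit(p)), p, tolerance = 1e-12)
  # deep tail: no underflow to exactly zero
  expect_gt(inv_logit(-50), 0)
  expect_equal(inv_logit(-50), 1.928749848e-22, tolerance = 1e-6)
  expect_error(logit(0), "inside")
  expect_error(logit(1), "inside")
  expect_error(inv_logit(Inf), "finite")
})

test_that("kernel predictions match hand-derived values and asymptote", {
  cf <- ref5()
  # at the source edge: logit = -3.50 + e^0.26 + e^1.59 = 2.7006
  expect_equal(round(predict_frequency(cf, 0), 4), 0.9371)
  # far-field asymptote is inv_logit(beta0) once both terms die off
  expect_equal(predict_frequency(cf, 1e6), inv_logit(-3.50),
               tolerance = 1e-6)
  expect_equal(round(inv_logit(-3.50), 3), 0.029)
  # constant model: two exp(0) terms on top of beta0 = 0 give inv_logit(2)
  const <- decay_coefficients(
    c(beta0 = 0, beta1 = 0, gamma1 = 0, beta2 = 0, gamma2 = 0),
    model_spec(2, "none", "none"))
  expect_equal(predict_frequency(const, c(0, 7, 300)),
               rep(inv_logit(2), 3))
  expect_equal(round(inv_logit(2), 4), 0.8808)
})

test_that("prediction is strictly decreasing when both rates decay", {
  set.seed(11)
  for (i in 1:25) {
    cf <- decay_coefficients(
      c(beta0 = runif(1, -5, -2), beta1 = runif(1, -1, 1),
        gamma1 = -exp(runif(1, -1, 1.5)), beta2 = runif(1, 0, 2),
        gamma2 = -exp(runif(1, -4, -1))),
      model_spec(2, "none", "none"))
    p <- predict_frequency(cf, seq(0, 60, by = 0.5))
    expect_true(all(diff(p) < 0))
  }
})

test_that("full-coding predictions use reference plus offsets", {
  cf <- reference_coefficients(full = TRUE)
  est <- cf$coef
  # NW arm in the second year, by hand from the printed offsets
  d <- 10
  b2 <- est[["beta2"]] + est[["beta2:directionNW"]] +
    est[["beta2:year2015"]] + est[["beta2:directionNW:year2015"]]
  g2 <- est[["gamma2"]] + est[["gamma2:directionNW"]] +
    est[["gamma2:year2015"]] + est[["gamma2:directionNW:year2015"]]
  eta <- est[["beta0"]] + exp(est[["beta1"]] + est[["gamma1"]] * d) +
    exp(b2 + g2 * d)
  expect_equal(predict_frequency(cf, d, "NW", "2015"), inv_logit(eta),
               tolerance = 1e-12)
  # reference arm needs no offsets
  expect_equal(predict_frequency(cf, 0, "E", "2014"),
               predict_frequency(ref5(), 0), tolerance = 1e-12)
  expect_error(predict_frequency(cf, 1), "direction")
})

test_that("negative log-likelihood equals the brute-force binomial sum", {
  rec <- toy_records()
  cf <- ref5()
  p <- predict_frequency(cf, rec$distance_m)
  oracle <- -sum(dbinom(rec$n_resistant, rec$n_screened, p, log = TRUE))
  expect_equal(pmgf_nll(cf, rec), oracle, tolerance = 1e-10)
  # saturation: a single all-resistant cell at p -> 1 contributes ~ 0
  sat <- as_screening_records(data.frame(
    year = 2014, direction = "E", distance_m = 0.001,
    n_screened = 50, n_resistant = 50))
  steep <- decay_coefficients(
    c(beta0 = 30, beta1 = 0, gamma1 = -1, beta2 = 0, gamma2 = -1),
    model_spec(2, "none", "none"))
  expect_lt(pmgf_nll(steep, sat), 1e-8)
})

test_that("the analytic gradient matches finite differences", {
  rec <- toy_records()
  spec <- model_spec(2, "direction+year", "year")
  mf <- pmgflow:::.model_frame(rec, spec)
  par <- pmgflow:::.start_values(mf)
  g <- pmgflow:::.grad_natural(par, mf)
  for (j in seq_along(par)) {
    h <- 1e-6 * max(abs(par[j]), 1)
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- par[j] - h
    fd <- (pmgflow:::.nll_natural(up, mf) -
             pmgflow:::.nll_natural(dn, mf)) / (2 * h)
    expect_equal(unname(g[j]), fd, tolerance = 1e-5)
  }
})

test_that("intercept-only MLE equals the pooled proportion exactly", {
  rec <- toy_records()[1:2, ]
  f <- fit_decay(rec, model_spec(0), n_starts = 2, seed = 1)
  pooled <- sum(rec$n_resistant) / sum(rec$n_screened)
  expect_equal(inv_logit(coef(f)[["beta0"]]), pooled, tolerance = 1e-10)
  expect_equal(f$k, 1)
})

test_that("fitting recovers a distance-only truth and reports honest AIC", {
  truth <- generator_truth(coefficients = ref5(),
                           years = 2014, n_per_cell = 5000, seed = 77)
  rec <- generate_screening(truth)
  f <- fit_decay(rec, model_spec(2, "none", "none"), n_starts = 4, seed = 5)
  expect_true(f$converged)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$k)
  s <- summary(f)
  truth_vec <- ref5()$coef[s$term]
  expect_true(all(abs(s$estimate - truth_vec) / s$std_error < 4))
  # fast-decay term labelled first
  expect_gte(abs(coef(f)[["gamma1"]]), abs(coef(f)[["gamma2"]]))
})

test_that("fit is invariant to record order and reference relabelling", {
  truth <- generator_truth(n_per_cell = 800, seed = 55)
  rec <- generate_screening(truth)
  spec <- model_spec(2, "direction", "none")
  f1 <- fit_decay(rec, spec, n_starts = 3, seed = 2)
  f2 <- fit_decay(rec[sample(nrow(rec)), ], spec, n_starts = 3, seed = 2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  # re-coding the reference direction leaves predictions unchanged
  f3 <- fit_decay(rec, model_spec(2, "direction", "none",
                                  ref_direction = "N"),
                  n_starts = 3, seed = 2)
  d <- c(0.5, 2, 15)
  for (dir in c("N", "E", "SW"))
    expect_equal(predict(f1, d, dir, "2014"), predict(f3, d, dir, "2014"),
                 tolerance = 1e-4)
})

test_that("a double spec on single-exponential truth wastes little likelihood", {
  single <- decay_coefficients(c(beta0 = -3.2, beta1 = 0.8, gamma1 = -0.25),
                               model_spec(1))
  truth <- generator_truth(coefficients = single, years = 2014,
                           n_per_cell = 3000, seed = 91)
  rec <- generate_screening(truth)
  f1 <- fit_decay(rec, model_spec(1), n_starts = 4, seed = 3)
  f2 <- fit_decay(rec, model_spec(2, "none", "none"), n_starts = 4, seed = 3)
  expect_gte(f2$loglik, f1$loglik - 1e-6)     # nesting
  expect_lt(f2$loglik - f1$loglik, 2)          # degenerate second term
})

test_that("Pearson chi-squared equals the hand-computed grouped statistic", {
  rec <- as_screening_records(data.frame(
    year = 2014, direction = c("E", "E", "E"), distance_m = c(1, 5, 20),
    n_screened = c(10, 20, 15), n_resistant = c(3, 5, 6)))
  # mu = n p: 2.5, 6, 7.5; chisq = 2.5/18.75 + 20/84 + 33.75/56.25
  gof <- pearson_gof(NULL, rec, fitted_p = c(0.25, 0.3, 0.5), k = 1)
  expect_equal(gof$chisq, 10 * 0.5^2 / (2.5 * 7.5) + 20 * 1 / (6 * 14) +
                 15 * 2.25 / (7.5 * 7.5), tolerance = 1e-10)
  expect_equal(gof$chisq, 0.9714285714, tolerance = 1e-9)
  expect_equal(gof$df, 1)

  # saturated fitted values reproduce the observations: chisq = 0
  sat <- pearson_gof(NULL, rec, fitted_p = rec$n_resistant / rec$n_screened,
                     k = 1)
  expect_equal(sat$chisq, 0)
})

test_that("dispersion is near 1 under the true model", {
  disp <- vapply(1:10, function(s) {
    truth <- generator_truth(coefficients = ref5(), years = 2014,
                             n_per_cell = 2000, seed = 700 + s)
    rec <- generate_screening(truth)
    f <- fit_decay(rec, model_spec(2, "none", "none"), n_starts = 2,
                   seed = s)
    pearson_gof(f, rec)$dispersion
  }, numeric(1))
  expect_gt(mean(disp), 0.6)
  expect_lt(mean(disp), 1.4)
})

test_that("degenerate fitted cells are excluded with a warning", {
  rec <- as_screening_records(data.frame(
    year = 2014, direction = "E", distance_m = c(1, 5, 9, 14),
    n_screened = 10, n_resistant = c(10, 5, 3, 1)))
  expect_warning(
    gof <- pearson_gof(NULL, rec, fitted_p = c(1, 0.5, 0.3, 0.1), k = 1),
    "degenerate")
  expect_equal(gof$n_cells, 3)
  expect_equal(gof$df, 1)
})
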