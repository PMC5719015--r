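test_that("reduction distances are monotone and meet the grid-search oracle", {
  set.seed(23)
  n_attain <- 0
  for (i in 1:50) {
    cf <- decay_coefficients(
      c(beta0 = runif(1, -5, -2.5), beta1 = runif(1, -0.5, 0.5),
        gamma1 = -exp(runif(1, 0.5, 1.7)), beta2 = runif(1, 0.5, 2),
        gamma2 = -exp(runif(1, -3.5, -1.5))),
      model_spec(2, "none", "none"))
    o50 <- reduction_distance(cf, reduction = 0.5,
                              reference_distance_m = 0.1)
    o90 <- reduction_distance(cf, reduction = 0.9,
                              reference_distance_m = 0.1)
    # a deep reduction may genuinely sit below the asymptote; when both are
    # attainable the ordering must hold
    if (!is.na(o90)) {
      expect_false(is.na(o50))
      expect_lt(o50, o90)
    }
    if (is.na(o50)) next
    n_attain <- n_attain + 1
    # grid-search oracle at 1e-4 m resolution through the vectorized
    # prediction path (independent of the scalar root-finder)
    target <- 0.5 * predict_frequency(cf, 0.1)
    coarse <- seq(0.1, 200, by = 0.01)
    hit <- coarse[which(predict_frequency(cf, coarse) <= target)[1]]
    fine <- seq(max(0.1, hit - 0.02), hit + 0.02, by = 1e-4)
    oracle <- fine[which(predict_frequency(cf, fine) <= target)[1]]
    expect_lt(abs(o50 - oracle), 1e-3)
  }
  expect_gte(n_attain, 30)   # the sweep must mostly exercise real roots
})

test_that("reduction distance approaches the baseline as reduction vanishes", {
  cf <- ref5()
  d <- vapply(c(0.2, 0.05, 0.005, 5e-4), function(r)
    reduction_distance(cf, reduction = r, reference_distance_m = 0.5),
    numeric(1))
  expect_true(all(diff(d) < 0))
  expect_lt(d[4] - 0.5, 0.05)
})

test_that("targets below the asymptote are flagged unattainable", {
  # shallow kernel: asymptote inv_logit(-1) = 0.27, p(0.1) ~ 0.68; a 90%
  # reduction would need p = 0.068 < asymptote
  cf <- decay_coefficients(
    c(beta0 = -1, beta1 = 0, gamma1 = -2, beta2 = 0.5, gamma2 = -0.1),
    model_spec(2, "none", "none"))
  out <- reduction_distance(cf, reduction = 0.9, reference_distance_m = 0.1)
  expect_true(is.na(out))
  expect_false(attr(out, "attainable"))
  ok <- reduction_distance(cf, reduction = 0.3, reference_distance_m = 0.1)
  expect_true(attr(ok, "attainable"))
})

test_that("slower decay pushes both reduction distances outward", {
  base <- c(beta0 = -3.5, beta1 = 0.26, gamma1 = -5.35, beta2 = 1.59)
  o <- t(vapply(c(-0.12, -0.06, -0.03), function(g2) {
    cf <- decay_coefficients(c(base, gamma2 = g2), model_spec(2, "none", "none"))
    c(o50 = as.numeric(reduction_distance(cf, reduction = 0.5,
                                          reference_distance_m = 0.1)),
      o90 = as.numeric(reduction_distance(cf, reduction = 0.9,
                                          reference_distance_m = 0.1)))
  }, numeric(2)))
  expect_true(all(diff(o[, "o50"]) > 0))
  expect_true(all(diff(o[, "o90"]) > 0))
  expect_true(all(o[, "o50"] < o[, "o90"]))
})

test_that("bootstrap interval collapses to the point estimate at zero vcov", {
  truth <- generator_truth(coefficients = ref5(), years = 2014,
                           n_per_cell = 2000, seed = 71)
  rec <- generate_screening(truth)
  f <- fit_decay(rec, model_spec(2, "none", "none"), n_starts = 2, seed = 6)
  k <- length(coef(f))
  f0 <- f
  f0$coefficients$vcov <- matrix(0, k, k,
                                 dimnames = list(names(coef(f)),
                                                 names(coef(f))))
  point <- reduction_distance(f, reduction = 0.5, reference_distance_m = 0.1)
  ci <- reduction_ci(f0, reduction = 0.5, reference_distance_m = 0.1,
                     n_boot = 200, seed = 3)
  expect_equal(unname(ci[["lower"]]), as.numeric(point), tolerance = 1e-6)
  expect_equal(unname(ci[["upper"]]), as.numeric(point), tolerance = 1e-6)
})

test_that("inflating the coefficient covariance widens the interval", {
  truth <- generator_truth(coefficients = ref5(), years = 2014,
                           n_per_cell = 2000, seed = 72)
  rec <- generate_screening(truth)
  f <- fit_decay(rec, model_spec(2, "none", "none"), n_starts = 2, seed = 6)
  wide <- 0
  for (s in 1:5) {
    ci1 <- reduction_ci(f, reduction = 0.5, reference_distance_m = 0.1,
                        n_boot = 400, seed = s)
    f4 <- f
    f4$coefficients$vcov <- 4 * f$coefficients$vcov
    ci4 <- reduction_ci(f4, reduction = 0.5, reference_distance_m = 0.1,
                        n_boot = 400, seed = s)
    if (ci4[["lower"]] <= ci1[["lower"]] && ci4[["upper"]] >= ci1[["upper"]])
      wide <- wide + 1
  }
  expect_gte(wide, 5 * 0.95)
  expect_identical(
    reduction_ci(f, reduction = 0.5, reference_distance_m = 0.1,
                 n_boot = 300, seed = 11),
    reduction_ci(f, reduction = 0.5, reference_distance_m = 0.1,
                 n_boot = 300, seed = 11))
})

test_that("bootstrap intervals cover the true reduction distance", {
  cf_true <- ref5()
  d_true <- reduction_distance(cf_true, reduction = 0.5,
                               reference_distance_m = 0.1)
  hits <- 0
  n_rep <- 60
  for (s in 1:n_rep) {
    truth <- generator_truth(coefficients = cf_true, years = 2014,
                             n_per_cell = 1500, seed = 900 + s)
    rec <- generate_screening(truth)
    # a rare replicate can end on a flat (singular-information) optimum;
    # it simply contributes no interval
    f <- suppressWarnings(fit_decay(rec, model_spec(2, "none", "none"),
                                    n_starts = 2, seed = s))
    if (is.null(f$coefficients$vcov)) next
    ci <- reduction_ci(f, reduction = 0.5, reference_distance_m = 0.1,
                       n_boot = 300, seed = s)
    if (ci[["lower"]] <= d_true && d_true <= ci[["upper"]]) hits <- hits + 1
  }
  # 95% nominal; binomial 3-SE band at 60 replicates is ~ +/- 0.085
  expect_gte(hits / n_rep, 0.85)
})

test_that("detection power follows the at-least-one-survivor law", {
  expect_equal(detection_power(1, 0.5), 0.5)
  expect_equal(detection_power(2, 0.5), 0.75)
  expect_gte(detection_power(1609, 0.001), 0.8)
  expect_lt(detection_power(1608, 0.001), 0.8)
  # strictly increasing in n and p
  expect_true(all(diff(detection_power(1:50, 0.05)) > 0))
  expect_true(all(diff(detection_power(10, c(0.01, 0.05, 0.2))) > 0))
})

test_that("minimum sample size: closed form equals the linear scan", {
  expect_identical(min_sample_size(0.5, 0.8), 3L)
  expect_identical(min_sample_size(0.001, 0.8), 1609L)
  scan_oracle <- function(p, target) {
    n <- 1
    while (1 - (1 - p)^n < target) n <- n + 1
    n
  }
  set.seed(31)
  for (i in 1:200) {
    p <- runif(1, 1e-4, 0.6)
    target <- runif(1, 0.5, 0.99)
    expect_identical(min_sample_size(p, target),
                     as.integer(scan_oracle(p, target)))
  }
  expect_error(min_sample_size(1e-6, 1 - 1e-9, n_max = 1e6), "exceeds")
})
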