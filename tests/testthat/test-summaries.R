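test_that("gene-flow frequency is the exact survivor ratio", {
  expect_equal(round(gene_flow_frequency(1546, 2591), 2), 0.60)
  expect_equal(round(gene_flow_frequency(2218, 5198), 2), 0.43)
  expect_identical(gene_flow_frequency(0, 100), 0)
  expect_error(gene_flow_frequency(1, 0), "undefined")
  expect_error(gene_flow_frequency(5, 3), "n_resistant")
})

test_that("pooling sums counts before taking the ratio", {
  set.seed(42)
  for (i in 1:20) {
    df <- data.frame(
      year = 2014, direction = sample(c("N", "E", "S", "W"), 6, TRUE),
      distance_m = 5, n_screened = sample(50:500, 6))
    df$n_resistant <- rbinom(6, df$n_screened, 0.3)
    pooled <- pooled_frequency_by_distance(df, exclude_cells = NULL)
    expect_equal(pooled$frequency,
                 sum(df$n_resistant) / sum(df$n_screened))
    mr <- pooled_frequency_by_distance(df, pooling = "mean_ratio",
                                       exclude_cells = NULL)
    expect_equal(mr$frequency, mean(df$n_resistant / df$n_screened))
  }
})

test_that("pooled table reproduces every published per-distance frequency", {
  tab <- published_counts()
  pooled <- pooled_frequency_by_distance(tab)
  expect_equal(nrow(pooled), 19)
  m <- merge(pooled, tab, by.x = c("year", "distance_m"),
             by.y = c("year", "distance_m"))
  # the published second-year 15 m row prints 0.10 against its own counts
  # (437/4782 = 0.0914); the count ratio is authoritative there
  odd <- m$year == "2015" & m$distance_m == 15
  expect_equal(round(m$frequency[!odd], 2), m$frequency_printed[!odd])
  expect_equal(round(m$frequency[odd], 2), 0.09)
  p2014 <- pooled_frequency_by_distance(tab, year = 2014)
  expect_equal(nrow(p2014), 9)
  expect_equal(sum(p2014$total_screened), 47702)
  expect_equal(sum(p2014$total_resistant), 7317)
})

test_that("the first-year 0.1 m cell is excluded by default from pooling", {
  df <- data.frame(year = c(2014, 2014), direction = "E",
                   distance_m = c(0.1, 0.5),
                   n_screened = c(10, 100), n_resistant = c(5, 50))
  expect_equal(nrow(pooled_frequency_by_distance(df)), 1)
  expect_equal(nrow(pooled_frequency_by_distance(df, exclude_cells = NULL)), 2)
})

test_that("synchrony conventions and capping behave as defined", {
  # receptors equal donor: perfect synchrony under both conventions
  expect_equal(flowering_synchrony(c(50, 50, 50), 50, "eq1"), 100)
  expect_equal(flowering_synchrony(c(50, 50, 50), 50, "table1"), 1)
  # hand arithmetic: (0.5 + 1 + 1.5 + 1)/4 * 100 = 100
  expect_equal(flowering_synchrony(c(25, 50, 75, 50), 50, "eq1"), 100)
  # capped version treats receptors at/above donor as fully synchronized
  expect_equal(flowering_synchrony(c(25, 50, 75, 50), 50, "eq1", cap = TRUE),
               mean(c(0.5, 1, 1, 1)) * 100)
  # order invariance
  x <- c(12, 99, 40, 73)
  expect_equal(flowering_synchrony(x, 60, "eq1"),
               flowering_synchrony(rev(x), 60, "eq1"))
  expect_error(flowering_synchrony(c(10, 20), 0, "eq1"), "donor")
  expect_error(flowering_synchrony(c(10, 0), 50, "table1"), "receptor")
})

test_that("wind rose bins half-open 45-degree sectors and sums to 100%", {
  base <- data.frame(air_temp_c = 20, precip_mm = 0, rh_pct = 60,
                     wind_speed_ms = 2)
  south <- cbind(timestamp = as.POSIXct("2014-08-01", tz = "UTC") + 3600 * 0:9,
                 base, wind_dir_deg = 180)
  rose <- wind_rose(as_weather_records(south))
  expect_equal(rose$frequency_pct[rose$sector == "S"], 100)
  expect_equal(sum(rose$frequency_pct), 100)
  expect_equal(rose$wind_run[rose$sector == "S"], 2)

  # boundary bearings belong to the clockwise-next sector
  edges <- cbind(timestamp = as.POSIXct("2014-08-01", tz = "UTC") + 3600 * 0:3,
                 base, wind_dir_deg = c(22.5, 337.5, 22.4999, 67.5))
  rose2 <- wind_rose(as_weather_records(edges))
  got <- rep(rose2$sector, rose2$n_hours)
  expect_equal(sort(got), sort(c("NE", "N", "N", "E")))

  expect_error(wind_rose(data.frame()), "empty")
})

test_that("wind-rose frequencies always sum to 100 before rounding", {
  for (s in 1:5) {
    wx <- generate_weather(generator_truth(n_per_cell = 1, seed = s),
                           weeks = 1)
    expect_equal(sum(wind_rose(wx)$frequency_pct), 100, tolerance = 1e-9)
  }
})

test_that("PMGF-wind correlation matches the textbook Pearson formula", {
  rose <- data.frame(sector = c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
                     frequency_pct = c(5, 5, 10, 20, 30, 10, 10, 10),
                     mean_speed_ms = c(1, 1.5, 2, 3, 3.5, 2, 1.8, 1.2))
  rose$wind_run <- rose$mean_speed_ms * rose$frequency_pct / 100
  df <- data.frame(year = 2014, direction = rose$sector, distance_m = 10,
                   n_screened = 1000)
  # frequencies exactly proportional to the downwind wind run -> r = 1
  run_downwind <- rose$wind_run[match(c("S", "SW", "W", "NW", "N", "NE",
                                        "E", "SE"), rose$sector)]
  df$n_resistant <- round(200 * run_downwind)
  out <- correlate_pmgf_wind(df, rose, parameter = "run",
                             mapping = "downwind")
  expect_equal(out$r, 1, tolerance = 1e-6)

  # anti-proportional -> r = -1
  df$n_resistant <- round(1000 - 200 * run_downwind)
  out2 <- correlate_pmgf_wind(df, rose, parameter = "run",
                              mapping = "downwind")
  expect_equal(out2$r, -1, tolerance = 1e-6)

  # brute-force Pearson r and its t-based p-value, to near machine precision
  set.seed(7)
  df$n_resistant <- rbinom(8, 1000, 0.2)
  out3 <- correlate_pmgf_wind(df, rose, parameter = "speed",
                              mapping = "sector")
  x <- df$n_resistant / df$n_screened
  w <- rose$mean_speed_ms[match(df$direction, rose$sector)]
  r_hand <- sum((x - mean(x)) * (w - mean(w))) /
    sqrt(sum((x - mean(x))^2) * sum((w - mean(w))^2))
  t_hand <- r_hand * sqrt(6 / (1 - r_hand^2))
  expect_equal(out3$r, r_hand, tolerance = 1e-12)
  expect_equal(out3$p_value, 2 * pt(-abs(t_hand), df = 6), tolerance = 1e-12)
})

test_that("zero-variance correlation inputs are flagged, not NaN", {
  rose <- data.frame(sector = c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
                     frequency_pct = 12.5, mean_speed_ms = 2, wind_run = 0.25)
  df <- data.frame(year = 2014, direction = rose$sector, distance_m = 10,
                   n_screened = 100, n_resistant = 5:12)
  out <- correlate_pmgf_wind(df, rose, parameter = "speed")
  expect_true(out$degenerate)
  expect_true(is.na(out$r))
})

test_that("direction-free kernels show no spurious wind correlation", {
  # null simulation: direction-independent truth, uniform wind
  rose <- data.frame(sector = c("N", "NE", "E", "SE", "S", "SW", "W", "NW"),
                     frequency_pct = 12.5, mean_speed_ms = seq(1, 3, length = 8))
  rose$wind_run <- rose$mean_speed_ms * rose$frequency_pct / 100
  rs <- vapply(1:20, function(s) {
    truth <- generator_truth(coefficients = ref5(),
                             design = field_design(
                               cardinal_distances_m = c(1, 10)),
                             years = 2014, n_per_cell = 500, seed = 500 + s)
    rec <- generate_screening(truth)
    out <- correlate_pmgf_wind(rec, rose, parameter = "speed")
    mean(out$r)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)   # ~0 under the null, SE ~ 0.08
})
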