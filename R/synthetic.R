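# Seeded synthetic data with the statistical structure the analysis assumes:
# binomial screening counts from the double-exponential logit kernel over the
# concentric design, an S/SE-prevailing hourly wind stream, and logistic
# flowering-progress curves. One root seed; per-stream child seeds are drawn
# once from the root so screening/weather/flowering are independently
# reproducible.

.child_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("screening", "weather", "flowering"))
}

#' Generating truth for the synthetic-data module
#'
#' Bundles everything the generators need: the kernel coefficients, the
#' field design, per-cell sample sizes, the wind-FROM sector distribution
#' and per-sector mean speeds, and the root seed. Defaults emulate the
#' source study's conditions: the packaged coefficient table as kernel, the
#' standard concentric design over two years, per-cell sample sizes from the
#' published per-distance screening totals split evenly over the eight
#' directions (per-direction sizes were not published), S/SE-prevailing
#' winds, and a 2.8 m/s mean sector speed.
#'
#' @param coefficients a [decay_coefficients()] object (the generative
#'   kernel).
#' @param design a [field_design()].
#' @param years study-year labels.
#' @param n_per_cell screened plants per (year, direction, distance) cell:
#'   a single number for all cells, or a data.frame with columns `year`,
#'   `distance_m`, `n` (split evenly across directions happens upstream of
#'   this table: `n` is already per cell). `NULL` (default) uses the
#'   packaged per-distance totals divided by 8 and rounded; design cells
#'   without a published total (0.1 m in the first year) are dropped,
#'   matching the analyzed dataset.
#' @param prevailing_sector_weights 8 non-negative weights (named by sector
#'   or in N, NE, E, SE, S, SW, W, NW order) summing to 1: the distribution
#'   of the sector the wind blows FROM.
#' @param mean_speed_ms per-sector mean wind speed, m/s (recycled).
#' @param seed root integer seed; child seeds for the three streams are
#'   derived from it deterministically.
#' @return object of class `"generator_truth"`.
#' @examples
#' truth <- generator_truth(n_per_cell = 100, seed = 42)
#' @export
generator_truth <- function(coefficients = reference_coefficients(),
                            design = field_design(),
                            years = c(2014, 2015),
                            n_per_cell = NULL,
                            prevailing_sector_weights = c(
                              N = 0.08, NE = 0.06, E = 0.08, SE = 0.20,
                              S = 0.28, SW = 0.12, W = 0.10, NW = 0.08),
                            mean_speed_ms = 2.8,
                            seed = 1) {
  stopifnot(inherits(coefficients, "decay_coefficients"),
            inherits(design, "field_design"))
  w <- prevailing_sector_weights
  if (is.null(names(w))) names(w) <- SECTORS
  stopifnot(length(w) == 8, all(SECTORS %in% names(w)))
  w <- w[SECTORS]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("prevailing_sector_weights must be non-negative and sum to 1",
         call. = FALSE)
  speed <- rep_len(as.numeric(mean_speed_ms), 8)
  names(speed) <- SECTORS
  if (any(speed <= 0)) stop("mean_speed_ms must be positive", call. = FALSE)
  if (!is.null(n_per_cell) && !is.data.frame(n_per_cell)) {
    stopifnot(is.numeric(n_per_cell), length(n_per_cell) == 1L,
              n_per_cell >= 0)
  }
  structure(
    list(coefficients = coefficients, design = design,
         years = as.character(years), n_per_cell = n_per_cell,
         prevailing_sector_weights = w, mean_speed_ms = speed,
         seed = as.integer(seed), child_seeds = .child_seeds(seed)),
    class = "generator_truth")
}

#' @export
print.generator_truth <- function(x, ...) {
  cat("PMGF generator truth (seed ", x$seed, ")\n", sep = "")
  cat("  kernel:", x$coefficients$spec$name, "\n")
  cat("  years: ", paste(x$years, collapse = ", "), "\n")
  invisible(x)
}

.truth_cells <- function(truth) {
  cells <- design_cells(truth$design, truth$years)
  npc <- truth$n_per_cell
  if (is.null(npc)) {
    tab <- published_counts()
    key <- paste(cells$year, cells$distance_m)
    idx <- match(key, paste(tab$year, tab$distance_m))
    # split each marginal over the arms actually planted at that distance
    # (8 for shared distances, 4 for the ordinal-only ones)
    arms <- as.numeric(table(key)[key])
    cells$n_screened <- as.integer(round(tab$n_screened[idx] / arms))
    drop <- is.na(cells$n_screened)
    if (any(drop)) {
      message(sprintf(
        "dropping %d design cell(s) with no published sample-size profile",
        sum(drop)))
      cells <- cells[!drop, , drop = FALSE]
    }
  } else if (is.data.frame(npc)) {
    .require_columns(npc, c("year", "distance_m", "n"), "n_per_cell table")
    idx <- match(paste(cells$year, cells$distance_m),
                 paste(as.character(npc$year), npc$distance_m))
    if (any(is.na(idx)))
      stop("n_per_cell table does not cover every design cell", call. = FALSE)
    cells$n_screened <- as.integer(npc$n[idx])
  } else {
    cells$n_screened <- as.integer(npc)
  }
  rownames(cells) <- NULL
  cells
}

#' Simulate screening counts from the decay kernel
#'
#' For every (year, direction, distance) cell of the design, draws the
#' number of resistant seedlings binomially with the probability the truth's
#' kernel predicts at that cell. Deterministic given the truth's seed.
#'
#' @param truth a [generator_truth()].
#' @return screening records (as from [read_screening()]) with attributes
#'   `seed` (root) and `stream_seed`, plus a `true_p` column attribute-free
#'   copy in `attr(, "true_p")`.
#' @examples
#' rec <- generate_screening(generator_truth(n_per_cell = 50, seed = 7))
#' head(rec)
#' @export
generate_screening <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  cells <- .truth_cells(truth)
  # overflow guard: name the first offending cell
  cf <- truth$coefficients
  mf <- .model_frame(cells, cf$spec, directions = cf$directions,
                     years = cf$years)
  args <- c(if (cf$spec$n_exp_terms >= 1)
    cf$coef[["beta1"]] + cf$coef[["gamma1"]] * mf$distance,
    if (cf$spec$n_exp_terms == 2)
      drop(mf$Xb %*% cf$coef[colnames(mf$Xb)]) +
      drop(mf$Xg %*% cf$coef[colnames(mf$Xg)]) * mf$distance)
  if (length(args) && max(args) > 700) {
    i <- ((which.max(args) - 1L) %% nrow(cells)) + 1L
    stop(sprintf(
      "kernel exponent overflows (> 700) at cell (%s, %s, %g m)",
      cells$year[i], cells$direction[i], cells$distance_m[i]), call. = FALSE)
  }
  p <- predict_frequency(cf, cells$distance_m, cells$direction, cells$year)
  set.seed(truth$child_seeds[["screening"]])
  cells$n_resistant <- stats::rbinom(nrow(cells), cells$n_screened, p)
  out <- as_screening_records(cells[, c("year", "direction", "distance_m",
                                        "n_screened", "n_resistant")])
  attr(out, "seed") <- truth$seed
  attr(out, "stream_seed") <- unname(truth$child_seeds[["screening"]])
  attr(out, "true_p") <- p
  out
}

#' Simulate an hourly weather stream
#'
#' Hourly records over `weeks` weeks from `start`. The wind-FROM sector is
#' drawn from the truth's prevailing-sector weights, the bearing uniformly
#' within the sector, and the speed from a gamma distribution (shape 2,
#' scale = sector mean / 2 -- a realistic right-skewed non-negative
#' marginal; only sector means are specified by the conditions the
#' generator emulates). Air temperature follows a diurnal sinusoid inside
#' the 17--30 degC flowering-period band; precipitation is a sparse
#' exponential process.
#'
#' @param truth a [generator_truth()].
#' @param start first day (coerced with [as.Date()]).
#' @param weeks number of whole weeks (>= 1).
#' @return weather records as from [read_weather()].
#' @export
generate_weather <- function(truth, start = "2014-07-25", weeks = 6) {
  stopifnot(inherits(truth, "generator_truth"))
  if (!is.numeric(weeks) || length(weeks) != 1L || weeks < 1)
    stop("`weeks` must be >= 1", call. = FALSE)
  set.seed(truth$child_seeds[["weather"]])
  n <- as.integer(weeks * 7 * 24)
  ts <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n) - 1)
  sector <- sample(SECTORS, n, replace = TRUE,
                   prob = truth$prevailing_sector_weights)
  centre <- (match(sector, SECTORS) - 1) * 45
  dir <- (centre + stats::runif(n, -22.5, 22.5)) %% 360
  speed <- stats::rgamma(n, shape = 2,
                         scale = truth$mean_speed_ms[sector] / 2)
  hour <- as.numeric(format(ts, "%H"))
  temp <- 23.5 + 5 * sin((hour - 9) / 24 * 2 * pi) + stats::rnorm(n, 0, 0.8)
  wet <- stats::runif(n) < 0.03
  precip <- ifelse(wet, round(stats::rexp(n, rate = 0.5), 1), 0)
  rh <- pmin(100, pmax(20, stats::rnorm(n, 70, 10)))
  as_weather_records(data.frame(
    timestamp = ts, air_temp_c = round(temp, 1), precip_mm = precip,
    rh_pct = round(rh, 1), wind_speed_ms = round(speed, 2),
    wind_dir_deg = round(dir, 1) %% 360))
}

#' Simulate flowering-progress observations
#'
#' Logistic rise-and-fall flowering curves observed at a fixed cadence for
#' the donor block and every receptor station. Receptor curves are the donor
#' curve scaled by `synchrony_target` (so with target 1 and no delay,
#' synchrony is exactly 100% at every date); stations at >= 10 m may flower
#' 3--6 days late (`delay_days`), emulating the delayed onset observed at
#' low-competition far stations. The donor's pollen-shed curve equals its
#' flowering curve shifted by `shed_lag_days` (default 0).
#'
#' @param design a [field_design()].
#' @param synchrony_target receptor/donor amplitude ratio in (0, 1].
#' @param seed integer seed (controls the per-station delays).
#' @param start first observation date.
#' @param n_obs number of observations per station.
#' @param cadence_days days between observations.
#' @param delay_days range of onset delay (days) applied at stations
#'   >= `delay_from_m`; `NULL` disables the delay.
#' @param delay_from_m distance from which the delay applies.
#' @param shed_lag_days lag of pollen shed behind donor flowering, days.
#' @return flowering records as from [read_flowering()].
#' @export
generate_flowering <- function(design = field_design(), synchrony_target = 1,
                               seed = 1, start = "2014-07-25", n_obs = 9,
                               cadence_days = 5, delay_days = c(3, 6),
                               delay_from_m = 10, shed_lag_days = 0) {
  stopifnot(inherits(design, "field_design"))
  if (!(synchrony_target > 0 && synchrony_target <= 1))
    stop("`synchrony_target` must be in (0, 1]", call. = FALSE)
  set.seed(.child_seeds(seed)[["flowering"]])
  t_obs <- (seq_len(n_obs) - 1) * cadence_days
  dates <- as.Date(start) + t_obs
  # rise-and-fall pulse: onset day 7, senescence day 35 (a 5-6 week season)
  pulse <- function(t, delay = 0)
    100 * stats::plogis((t - 7 - delay) / 3) * stats::plogis((35 - t) / 4)
  donor <- data.frame(
    date = dates, block_type = "donor", direction = NA_character_,
    distance_m = NA_real_,
    pct_flowering = round(pulse(t_obs), 1),
    pct_shedding = round(pulse(t_obs - shed_lag_days), 1))
  stations <- design_cells(design, years = "x")[, c("direction", "distance_m")]
  rec <- do.call(rbind, lapply(seq_len(nrow(stations)), function(i) {
    delay <- 0
    if (!is.null(delay_days) && stations$distance_m[i] >= delay_from_m)
      delay <- stats::runif(1, delay_days[1], delay_days[2])
    data.frame(
      date = dates, block_type = "receptor",
      direction = stations$direction[i],
      distance_m = stations$distance_m[i],
      pct_flowering = round(synchrony_target * pulse(t_obs, delay), 1),
      pct_shedding = NA_real_)
  }))
  as_flowering_records(rbind(donor, rec))
}
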