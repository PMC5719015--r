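# Derived dispersal quantities: O50/O90 reduction distances with bootstrap
# confidence intervals, and binomial detection power / minimum sample size.

# Collapse one direction-year arm to scalar kernel coefficients so the root
# finder evaluates p(d) without rebuilding design matrices per call.
.arm_predictor <- function(object, direction, year, wind = NULL) {
  cf <- .as_coefficients(object)
  spec <- cf$spec
  if (is.null(direction)) direction <- cf$directions[1]
  if (is.null(year)) year <- cf$years[1]
  cells <- data.frame(year = as.character(year),
                      direction = as.character(direction), distance_m = 0)
  mf <- .model_frame(cells, spec, wind = wind, directions = cf$directions,
                     years = cf$years)
  b0 <- cf$coef[["beta0"]]
  t1 <- spec$n_exp_terms >= 1
  b1 <- if (t1) cf$coef[["beta1"]] else 0
  g1 <- if (t1) cf$coef[["gamma1"]] else 0
  t2 <- spec$n_exp_terms == 2
  b2 <- if (t2) drop(mf$Xb %*% cf$coef[colnames(mf$Xb)]) else 0
  g2 <- if (t2) drop(mf$Xg %*% cf$coef[colnames(mf$Xg)]) else 0
  function(d)
    stats::plogis(b0 + (if (t1) exp(b1 + g1 * d) else 0) +
                    (if (t2) exp(b2 + g2 * d) else 0))
}

#' Distance at which gene flow falls by a given fraction
#'
#' Solves p(d*) = (1 - reduction) * p(reference) for d* > reference, where
#' p(.) is the model-predicted gene-flow frequency along one direction-year
#' arm. The reduction is multiplicative on the probability scale relative
#' to the frequency predicted at the closest analyzed distance (the
#' default baseline convention; pass `reference_distance_m = 0` for a
#' donor-edge baseline). The root is bracketed by geometric extension of
#' the upper end and found with [stats::uniroot()] to 1e-6 m.
#'
#' If the model's frequency never falls below the target on any distance --
#' the asymptote `inv_logit(beta0)` exceeds it, or the arm does not decay --
#' the target is unattainable and `NA` is returned with attribute
#' `attainable = FALSE` (published analyses note some 90% reductions lie
#' beyond the measured design, so this is a real outcome, not an error).
#'
#' @param object a [decay_coefficients()] or fitted model.
#' @param direction,year arm labels (omit for factor-free models).
#' @param reduction fraction in (0, 1): 0.5 gives O50, 0.9 gives O90.
#' @param reference_distance_m baseline distance, m (>= 0).
#' @param d_max largest distance considered before declaring the target
#'   unattainable, m.
#' @param wind wind summary for wind-covariate models.
#' @return distance in meters (scalar), with attribute `attainable`.
#' @examples
#' cf <- reference_coefficients(full = FALSE)
#' reduction_distance(cf, reduction = 0.5, reference_distance_m = 0.1)
#' @export
reduction_distance <- function(object, direction = NULL, year = NULL,
                               reduction = 0.5, reference_distance_m = 0.1,
                               d_max = 1e4, wind = NULL) {
  stopifnot(reduction > 0, reduction < 1, reference_distance_m >= 0)
  p_at <- .arm_predictor(object, direction, year, wind)
  p_ref <- p_at(reference_distance_m)
  target <- (1 - reduction) * p_ref
  # geometric bracket extension
  lo <- reference_distance_m
  hi <- max(2 * max(lo, 1), 10)
  while (p_at(hi) > target && hi < d_max) hi <- hi * 2
  if (p_at(hi) > target) {
    out <- NA_real_
    attr(out, "attainable") <- FALSE
    return(out)
  }
  root <- stats::uniroot(function(d) p_at(d) - target, lower = lo,
                         upper = min(hi, d_max * 2), tol = 1e-6)$root
  attr(root, "attainable") <- TRUE
  root
}

#' Parametric-bootstrap confidence interval for a reduction distance
#'
#' Draws coefficient vectors from the fit's asymptotic multivariate normal
#' (estimate, vcov), recomputes the reduction distance for each draw, and
#' reports the 2.5 and 97.5 percentiles (or `(1 - level)/2` tails).
#' Unattainable draws are counted and dropped; if more than half the draws
#' are unattainable the interval is flagged unreliable.
#'
#' @param fit a fitted model from [fit_decay()] with a valid vcov.
#' @inheritParams reduction_distance
#' @param n_boot number of bootstrap draws (>= 200).
#' @param seed integer seed; the interval is deterministic given it.
#' @param level confidence level.
#' @return numeric `c(lower, upper)` with attributes `n_unattainable` and
#'   `unreliable`.
#' @export
reduction_ci <- function(fit, direction = NULL, year = NULL, reduction = 0.5,
                         reference_distance_m = 0.1, n_boot = 1000,
                         seed = 1, level = 0.95, d_max = 1e4) {
  stopifnot(inherits(fit, "pmgf_fit"), n_boot >= 200)
  cf <- fit$coefficients
  if (is.null(cf$vcov))
    stop("fit has no coefficient covariance; cannot bootstrap", call. = FALSE)
  set.seed(seed)
  draws <- MASS::mvrnorm(n_boot, mu = cf$coef, Sigma = cf$vcov)
  dstar <- vapply(seq_len(n_boot), function(b) {
    cb <- decay_coefficients(draws[b, ], cf$spec, directions = cf$directions,
                             years = cf$years)
    reduction_distance(cb, direction, year, reduction, reference_distance_m,
                       d_max = d_max, wind = fit$wind)
  }, numeric(1))
  n_bad <- sum(is.na(dstar))
  ci <- stats::quantile(dstar, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- c(lower = ci[1], upper = ci[2])
  attr(out, "n_unattainable") <- n_bad
  attr(out, "unreliable") <- n_bad > n_boot / 2
  if (n_bad > n_boot / 2)
    warning("more than half of the bootstrap draws were unattainable; ",
            "interval unreliable", call. = FALSE)
  out
}

#' O50/O90 table over direction-year arms
#'
#' Convenience wrapper producing one row per direction and year with the
#' 50% and 90% reduction distances and their bootstrap intervals.
#'
#' @param fit fitted model from [fit_decay()].
#' @param directions,years arms to tabulate.
#' @param reference_distance_m named per-year baseline distances (recycled
#'   if scalar).
#' @inheritParams reduction_ci
#' @return data.frame with columns `direction`, `year`, `o50_m`,
#'   `o50_lower`, `o50_upper`, `o90_m`, `o90_lower`, `o90_upper`,
#'   `attainable_o50`, `attainable_o90`.
#' @export
reduction_table <- function(fit, directions = fit$coefficients$directions,
                            years = fit$coefficients$years,
                            reference_distance_m = 0.1, n_boot = 1000,
                            seed = 1) {
  ref <- rep_len(reference_distance_m, length(years))
  names(ref) <- years
  rows <- list()
  for (yr in years) for (dir in directions) {
    o50 <- reduction_distance(fit, dir, yr, 0.5, ref[[yr]])
    o90 <- reduction_distance(fit, dir, yr, 0.9, ref[[yr]])
    ci50 <- ci90 <- c(lower = NA_real_, upper = NA_real_)
    if (!is.null(fit$coefficients$vcov)) {
      if (!is.na(o50))
        ci50 <- reduction_ci(fit, dir, yr, 0.5, ref[[yr]], n_boot, seed)
      if (!is.na(o90))
        ci90 <- reduction_ci(fit, dir, yr, 0.9, ref[[yr]], n_boot, seed)
    }
    rows[[paste(yr, dir)]] <- data.frame(
      direction = dir, year = yr,
      o50_m = as.numeric(o50), o50_lower = ci50[["lower"]],
      o50_upper = ci50[["upper"]],
      o90_m = as.numeric(o90), o90_lower = ci90[["lower"]],
      o90_upper = ci90[["upper"]],
      attainable_o50 = isTRUE(attr(o50, "attainable")),
      attainable_o90 = isTRUE(attr(o90, "attainable")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binomial detection power
#'
#' Probability of observing at least one resistant survivor among `n`
#' screened seedlings when the true gene-flow frequency is `p`:
#' `1 - (1 - p)^n`. This at-least-one-detection formulation is the
#' package's explicit power model for rare binomial events.
#'
#' @param n number of seedlings screened (>= 1, vectorized).
#' @param true_frequency assumed gene-flow frequency in (0, 1).
#' @return power in \[0, 1\].
#' @examples
#' detection_power(1, 0.5)        # 0.5
#' detection_power(1609, 0.001)   # just over 0.8
#' @export
detection_power <- function(n, true_frequency) {
  stopifnot(all(n >= 1), all(true_frequency > 0), all(true_frequency < 1))
  -expm1(n * log1p(-true_frequency))
}

#' Minimum sample size for a target detection power
#'
#' Smallest `n` with `detection_power(n, p) >= power_target`; the closed
#' form is `ceiling(log(1 - power_target) / log(1 - p))`, adjusted by one
#' if floating point puts the boundary on the wrong side.
#'
#' @param true_frequency assumed gene-flow frequency in (0, 1).
#' @param power_target required power in (0, 1).
#' @param alpha significance level carried for reporting alongside the
#'   sample size; the at-least-one-detection power model itself involves
#'   only `p` and the target power.
#' @param n_max guard cap: an error is raised if the requirement exceeds
#'   it (the sample size diverges as `power_target` approaches 1).
#' @return integer sample size.
#' @examples
#' min_sample_size(0.5, 0.8)     # 3
#' min_sample_size(0.001, 0.8)   # 1609
#' @export
min_sample_size <- function(true_frequency, power_target = 0.8,
                            alpha = 0.05, n_max = 1e8) {
  stopifnot(true_frequency > 0, true_frequency < 1,
            power_target > 0, power_target < 1,
            alpha > 0, alpha < 1)
  n <- ceiling(log1p(-power_target) / log1p(-true_frequency))
  n <- max(n, 1)
  # floating-point boundary adjustment
  while (detection_power(n, true_frequency) < power_target) n <- n + 1
  while (n > 1 && detection_power(n - 1, true_frequency) >= power_target)
    n <- n - 1
  if (n > n_max)
    stop(sprintf("required sample size %d exceeds n_max = %g", n, n_max),
         call. = FALSE)
  as.integer(n)
}
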