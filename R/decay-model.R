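# Double exponential decay binomial logit dispersal model.
#
# logit(p_i) = beta0 + exp(beta1 + gamma1 * d_i)
#                    + exp(beta2_i + gamma2_i * d_i)
#
# where the second term's intercept (beta2_i) and decay rate (gamma2_i) may
# be coded by direction, year, their interaction, and/or a per-direction wind
# covariate. Fitting is direct maximum likelihood on the grouped binomial
# counts with an analytic gradient and seeded multi-start BFGS.

#' Logit and inverse logit
#'
#' `logit(p) = ln(p / (1 - p))`; `inv_logit(eta) = e^eta / (1 + e^eta)`.
#' Thin, domain-checked wrappers over [stats::qlogis()] / [stats::plogis()],
#' which are numerically stable for |eta| far beyond the overflow range of a
#' naive `exp(eta)/(1 + exp(eta))` (e.g. `inv_logit(-50)` is ~1.9e-22, not 0).
#'
#' @param p proportion(s) strictly inside (0, 1).
#' @param eta finite real value(s) on the log-odds scale.
#' @return numeric vector.
#' @examples
#' logit(0.5)                # 0
#' round(inv_logit(2.7006), 4)
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("logit() requires p strictly inside (0, 1)", call. = FALSE)
  stats::qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(eta) {
  if (any(!is.finite(eta)))
    stop("inv_logit() requires finite input", call. = FALSE)
  stats::plogis(eta)
}

# ---- model specification -----------------------------------------------

.T2_CHOICES <- c("none", "year", "direction", "direction+year",
                 "direction:year")

.t2_formula <- function(choice) {
  switch(choice,
         "none" = ~1,
         "year" = ~year,
         "direction" = ~direction,
         "direction+year" = ~direction + year,
         "direction:year" = ~direction * year)
}

#' Specify one candidate dispersal model
#'
#' A candidate model is defined by the number of exponential terms on the
#' logit scale (0 = intercept-only, 1 = single exponential decay, 2 = double
#' exponential decay), the factor coding of the second term's intercept and
#' decay rate, and an optional per-direction wind covariate on the second
#' term's intercept. Wind covariates and direction factors are mutually
#' exclusive (they explain the same between-arm variation and are treated
#' as collinear).
#'
#' @param n_exp_terms 0, 1 or 2.
#' @param t2_intercept,t2_decay factor coding of the second term, one of
#'   `"none"`, `"year"`, `"direction"`, `"direction+year"`,
#'   `"direction:year"` (the last expands to main effects + interaction).
#'   Ignored unless `n_exp_terms == 2`.
#' @param wind `NULL` or one of `"speed"`, `"frequency"`, `"run"`: a scalar
#'   per-direction wind summary entering the second-term intercept linearly.
#' @param wind_mapping how a wind-FROM sector summary is assigned to a
#'   receptor arm: `"downwind"` (arm d gets the summary of the opposite
#'   sector -- pollen travels downwind) or `"sector"` (same sector).
#' @param ref_direction reference direction for treatment contrasts.
#' @return an object of class `"pmgf_model_spec"`.
#' @examples
#' model_spec(2, "direction:year", "direction:year")  # the full model
#' @export
model_spec <- function(n_exp_terms = 2,
                       t2_intercept = "none",
                       t2_decay = "none",
                       wind = NULL,
                       wind_mapping = c("downwind", "sector"),
                       ref_direction = "E") {
  stopifnot(n_exp_terms %in% 0:2)
  t2_intercept <- match.arg(t2_intercept, .T2_CHOICES)
  t2_decay <- match.arg(t2_decay, .T2_CHOICES)
  wind_mapping <- match.arg(wind_mapping)
  if (!is.null(wind)) {
    wind <- match.arg(wind, c("speed", "frequency", "run"))
    if (grepl("direction", t2_intercept) || grepl("direction", t2_decay))
      stop("wind covariates and direction factors are collinear; ",
           "use one or the other", call. = FALSE)
    if (n_exp_terms < 2)
      stop("wind covariates enter the second exponential term; ",
           "set n_exp_terms = 2", call. = FALSE)
  }
  if (n_exp_terms < 2) {
    t2_intercept <- "none"
    t2_decay <- "none"
  }
  ref_direction <- match.arg(ref_direction, SECTORS)
  name <- if (n_exp_terms == 0) "const" else if (n_exp_terms == 1) "sexp" else
    paste0("dexp|b2:", t2_intercept, "|g2:", t2_decay,
           if (!is.null(wind)) paste0("|wind:", wind) else "")
  structure(
    list(n_exp_terms = n_exp_terms, t2_intercept = t2_intercept,
         t2_decay = t2_decay, wind = wind, wind_mapping = wind_mapping,
         ref_direction = ref_direction, name = name),
    class = "pmgf_model_spec")
}

#' @export
print.pmgf_model_spec <- function(x, ...) {
  cat("PMGF candidate model:", x$name, "\n")
  invisible(x)
}

# ---- coefficients -------------------------------------------------------

#' Assemble a decay-model coefficient set
#'
#' Coefficients are stored as a single named vector using treatment-contrast
#' term names (`beta0`, `beta1`, `gamma1`, `beta2`, `gamma2`,
#' `beta2:directionN`, `gamma2:directionNW:year2015`, ...; the bare `beta2` /
#' `gamma2` are the reference level, East in the first year). Together with
#' the generating [model_spec()] and the factor levels this is sufficient to
#' predict at any design point.
#'
#' @param coef named numeric vector of coefficients.
#' @param spec the [model_spec()] the names conform to.
#' @param directions direction levels, reference first.
#' @param years year labels, reference (first year) first.
#' @param vcov optional covariance matrix of the coefficients (rows/columns
#'   in `names(coef)` order).
#' @return object of class `"decay_coefficients"`.
#' @seealso [reference_coefficients()] for the packaged published values.
#' @export
decay_coefficients <- function(coef, spec, directions = NULL,
                               years = c("2014", "2015"), vcov = NULL) {
  stopifnot(inherits(spec, "pmgf_model_spec"), is.numeric(coef),
            !is.null(names(coef)))
  if (is.null(directions))
    directions <- c(spec$ref_direction, setdiff(SECTORS, spec$ref_direction))
  expected <- .term_names(spec, directions, as.character(years))
  missing <- setdiff(expected, names(coef))
  if (length(missing))
    stop("missing coefficient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  coef <- coef[expected]
  if (!is.null(vcov)) {
    stopifnot(is.matrix(vcov), nrow(vcov) == length(coef),
              ncol(vcov) == length(coef))
    dimnames(vcov) <- list(expected, expected)
  }
  structure(list(coef = coef, spec = spec, directions = directions,
                 years = as.character(years), vcov = vcov),
            class = "decay_coefficients")
}

#' @export
print.decay_coefficients <- function(x, digits = 4, ...) {
  cat("Decay-model coefficients (", x$spec$name, "), ",
      length(x$coef), " terms\n", sep = "")
  print(round(x$coef, digits))
  invisible(x)
}

# Expected coefficient names for a spec, in canonical order.
.term_names <- function(spec, directions, years) {
  out <- "beta0"
  if (spec$n_exp_terms >= 1) out <- c(out, "beta1", "gamma1")
  if (spec$n_exp_terms == 2) {
    grid <- .level_grid(directions, years)
    bcols <- colnames(.t2_design(spec$t2_intercept, grid))
    gcols <- colnames(.t2_design(spec$t2_decay, grid))
    if (!is.null(spec$wind)) bcols <- c(bcols, "wind")
    out <- c(out, .prefix_terms("beta2", bcols), .prefix_terms("gamma2", gcols))
  }
  out
}

.level_grid <- function(directions, years) {
  g <- expand.grid(direction = directions, year = years,
                   stringsAsFactors = FALSE)
  g$direction <- factor(g$direction, levels = directions)
  g$year <- factor(g$year, levels = years)
  g
}

.t2_design <- function(choice, data) {
  stats::model.matrix(.t2_formula(choice), data)
}

.prefix_terms <- function(prefix, cols) {
  ifelse(cols == "(Intercept)", prefix, paste0(prefix, ":", cols))
}

#' Published reference coefficients
#'
#' Builds a [decay_coefficients()] object from the packaged coefficient table
#' ([published_coefficients()]). With `full = TRUE` (default) all 35 printed terms are
#' used with the full direction-by-year coding; with `full = FALSE` only the
#' five reference-level values (beta0 = -3.50, beta1 = 0.26, gamma1 = -5.35,
#' beta2 = 1.59, gamma2 = -0.03) enter a distance-only double-exponential
#' model, the variant used in worked prediction examples.
#'
#' @param full use the complete printed coefficient set?
#' @return a `"decay_coefficients"` object.
#' @examples
#' round(predict_frequency(reference_coefficients(FALSE), 0), 4)  # 0.9371
#' @export
reference_coefficients <- function(full = TRUE) {
  tab <- published_coefficients()
  est <- stats::setNames(tab$estimate, tab$term)
  if (full) {
    spec <- model_spec(2, "direction:year", "direction:year")
    decay_coefficients(est, spec)
  } else {
    spec <- model_spec(2, "none", "none")
    decay_coefficients(est[c("beta0", "beta1", "gamma1", "beta2", "gamma2")],
                       spec)
  }
}

# ---- model frame and linear algebra ------------------------------------

# Build the per-cell matrices a spec needs from a cells data.frame with
# columns year, direction, distance_m (and n/y when fitting).
# `wind` is a wind_rose() summary table used only for wind-covariate specs.
.model_frame <- function(cells, spec, wind = NULL,
                         directions = NULL, years = NULL) {
  if (is.null(directions)) {
    present <- unique(as.character(cells$direction))
    directions <- c(intersect(spec$ref_direction, present),
                    setdiff(present[order(match(present, SECTORS))],
                            spec$ref_direction))
    if (!spec$ref_direction %in% present) directions <- present
  }
  if (is.null(years)) years <- sort(unique(as.character(cells$year)))
  d <- data.frame(
    direction = factor(as.character(cells$direction), levels = directions),
    year = factor(as.character(cells$year), levels = years),
    stringsAsFactors = FALSE)
  if (any(is.na(d$direction)) || any(is.na(d$year)))
    stop("cells contain direction or year levels unknown to the model",
         call. = FALSE)
  mf <- list(spec = spec, directions = directions, years = years,
             distance = as.numeric(cells$distance_m),
             n = if ("n_screened" %in% names(cells)) cells$n_screened,
             y = if ("n_resistant" %in% names(cells)) cells$n_resistant)
  if (spec$n_exp_terms == 2) {
    Xb <- .t2_design(spec$t2_intercept, d)
    Xg <- .t2_design(spec$t2_decay, d)
    colnames(Xb) <- .prefix_terms("beta2", colnames(Xb))
    colnames(Xg) <- .prefix_terms("gamma2", colnames(Xg))
    if (!is.null(spec$wind)) {
      wvals <- .wind_covariate(spec, wind, as.character(d$direction))
      Xb <- cbind(Xb, "beta2:wind" = wvals)
    }
    mf$Xb <- Xb
    mf$Xg <- Xg
  }
  mf$terms <- c("beta0",
                if (spec$n_exp_terms >= 1) c("beta1", "gamma1"),
                if (spec$n_exp_terms == 2) c(colnames(mf$Xb),
                                             colnames(mf$Xg)))
  mf
}

.wind_covariate <- function(spec, wind, directions) {
  if (is.null(wind))
    stop("model spec '", spec$name, "' needs a wind summary table",
         call. = FALSE)
  col <- switch(spec$wind, speed = "mean_speed_ms",
                frequency = "frequency_pct", run = "wind_run")
  sec <- if (spec$wind_mapping == "downwind")
    OPPOSITE_SECTOR[directions] else directions
  val <- wind[[col]][match(sec, as.character(wind$sector))]
  if (any(is.na(val)))
    stop("wind summary lacks sector(s): ",
         paste(unique(sec[is.na(val)]), collapse = ", "), call. = FALSE)
  as.numeric(val)
}

# Exponent cap: keeps the likelihood finite under wild optimizer excursions.
# The cap is far above any exponent reachable at realistic coefficients, and
# the gradient is zeroed beyond it so fn/gr stay mutually consistent.
.EXP_CAP <- 40

.eta_parts <- function(par, mf) {
  eta <- rep(par[["beta0"]], length(mf$distance))
  E1 <- E2 <- NULL
  if (mf$spec$n_exp_terms >= 1) {
    a1 <- par[["beta1"]] + par[["gamma1"]] * mf$distance
    E1 <- exp(pmin(a1, .EXP_CAP))
    attr(E1, "capped") <- a1 >= .EXP_CAP
    eta <- eta + E1
  }
  if (mf$spec$n_exp_terms == 2) {
    cb <- par[colnames(mf$Xb)]
    cg <- par[colnames(mf$Xg)]
    a2 <- drop(mf$Xb %*% cb) + drop(mf$Xg %*% cg) * mf$distance
    E2 <- exp(pmin(a2, .EXP_CAP))
    attr(E2, "capped") <- a2 >= .EXP_CAP
    eta <- eta + E2
  }
  list(eta = eta, E1 = E1, E2 = E2)
}

.nll_natural <- function(par, mf) {
  parts <- .eta_parts(par, mf)
  eta <- parts$eta
  # full binomial log-likelihood, constant included so AICs are comparable;
  # y*log(p) and (n-y)*log(1-p) are defined as 0 when their count is 0
  logp <- stats::plogis(eta, log.p = TRUE)
  log1mp <- stats::plogis(-eta, log.p = TRUE)
  ll <- lchoose(mf$n, mf$y) +
    ifelse(mf$y == 0, 0, mf$y * logp) +
    ifelse(mf$n == mf$y, 0, (mf$n - mf$y) * log1mp)
  -sum(ll)
}

.grad_natural <- function(par, mf) {
  parts <- .eta_parts(par, mf)
  w <- mf$n * stats::plogis(parts$eta) - mf$y   # dNLL/deta_i
  g <- stats::setNames(numeric(length(mf$terms)), mf$terms)
  g[["beta0"]] <- sum(w)
  if (mf$spec$n_exp_terms >= 1) {
    E1 <- ifelse(attr(parts$E1, "capped"), 0, parts$E1)
    g[["beta1"]] <- sum(w * E1)
    g[["gamma1"]] <- sum(w * E1 * mf$distance)
  }
  if (mf$spec$n_exp_terms == 2) {
    E2 <- ifelse(attr(parts$E2, "capped"), 0, parts$E2)
    g[colnames(mf$Xb)] <- drop(crossprod(mf$Xb, w * E2))
    g[colnames(mf$Xg)] <- drop(crossprod(mf$Xg, w * E2 * mf$distance))
  }
  g
}

#' Predict gene-flow frequency from a decay model
#'
#' Evaluates p = inv_logit(beta0 + exp(beta1 + gamma1 d) +
#' exp(beta2_dy + gamma2_dy d)) at the requested design points, where the
#' second-term intercept and rate are the reference values plus any
#' direction/year offsets the model codes.
#'
#' @param object a [decay_coefficients()] object or a fitted model from
#'   [fit_decay()].
#' @param distance_m distances from the donor edge, m (vectorized).
#' @param direction,year design-point labels; may be omitted when the model
#'   codes no factors.
#' @param wind wind summary table, only for wind-covariate models.
#' @return vector of predicted frequencies in (0, 1).
#' @examples
#' cf <- reference_coefficients(full = FALSE)
#' round(predict_frequency(cf, c(0, 1, 10, 50)), 4)
#' @export
predict_frequency <- function(object, distance_m, direction = NULL,
                              year = NULL, wind = NULL) {
  cf <- .as_coefficients(object)
  spec <- cf$spec
  k <- length(distance_m)
  if (is.null(direction)) {
    if (grepl("direction", spec$t2_intercept) ||
        grepl("direction", spec$t2_decay) || !is.null(spec$wind))
      stop("this model codes direction; supply `direction`", call. = FALSE)
    direction <- rep(cf$directions[1], k)
  }
  if (is.null(year)) {
    if (grepl("year", spec$t2_intercept) || grepl("year", spec$t2_decay))
      stop("this model codes year; supply `year`", call. = FALSE)
    year <- rep(cf$years[1], k)
  }
  cells <- data.frame(year = rep_len(as.character(year), k),
                      direction = .canonical_direction(rep_len(direction, k),
                                                       "prediction"),
                      distance_m = as.numeric(distance_m))
  mf <- .model_frame(cells, spec, wind = wind, directions = cf$directions,
                     years = cf$years)
  as.numeric(stats::plogis(.eta_parts(cf$coef, mf)$eta))
}

.as_coefficients <- function(object) {
  if (inherits(object, "decay_coefficients")) return(object)
  if (inherits(object, "pmgf_fit")) return(object$coefficients)
  stop("expected a decay_coefficients or pmgf_fit object", call. = FALSE)
}

#' Binomial negative log-likelihood of a decay model
#'
#' The full grouped-binomial negative log-likelihood (binomial coefficient
#' included, so likelihoods and AICs are comparable across every candidate
#' model) of a coefficient set on a table of screening records.
#'
#' @inheritParams predict_frequency
#' @param records screening records ([read_screening()] /
#'   [generate_screening()]).
#' @return scalar negative log-likelihood.
#' @export
pmgf_nll <- function(object, records, wind = NULL) {
  cf <- .as_coefficients(object)
  mf <- .model_frame(records, cf$spec, wind = wind,
                     directions = cf$directions, years = cf$years)
  .nll_natural(cf$coef, mf)
}

# ---- fitting ------------------------------------------------------------

# theta <-> natural: with constraints on, the REFERENCE decay rates are
# parameterized gamma = -exp(theta) (soft negativity constraint); factor
# offsets stay unconstrained, so per-level rates may still be positive, as
# observed in sparse arms.
.constrained_idx <- function(mf) {
  idx <- character()
  if (mf$spec$n_exp_terms >= 1) idx <- c(idx, "gamma1")
  if (mf$spec$n_exp_terms == 2) idx <- c(idx, "gamma2")
  intersect(idx, mf$terms)
}

.to_theta <- function(par, cidx) {
  th <- par
  th[cidx] <- log(-par[cidx])
  th
}

.to_natural <- function(theta, cidx) {
  par <- theta
  par[cidx] <- -exp(theta[cidx])
  par
}

.start_values <- function(mf, gamma1 = -1) {
  # beta0 from the far-field pooled frequency, second-term intercept from
  # the near-field pooled frequency minus beta0, decay rates at `gamma1`
  # and -0.05
  ord <- order(mf$distance)
  far <- ord[mf$distance[ord] >= stats::quantile(mf$distance, 0.75)]
  near <- ord[mf$distance[ord] <= stats::quantile(mf$distance, 0.25)]
  pool <- function(i) {
    p <- (sum(mf$y[i]) + 0.5) / (sum(mf$n[i]) + 1)
    stats::qlogis(min(max(p, 1e-6), 1 - 1e-6))
  }
  b0 <- pool(far)
  delta <- max(pool(near) - b0, 0.2)
  par <- stats::setNames(numeric(length(mf$terms)), mf$terms)
  par[["beta0"]] <- b0
  if (mf$spec$n_exp_terms >= 1) {
    par[["beta1"]] <- log(delta / if (mf$spec$n_exp_terms == 2) 2 else 1) - 1
    par[["gamma1"]] <- gamma1
  }
  if (mf$spec$n_exp_terms == 2) {
    par[["beta2"]] <- log(delta / 2)
    par[["gamma2"]] <- -0.05
  }
  par
}

# Deterministic starting points. The first exponential's spike can be much
# steeper than any generic start (a near-source term dying within a metre),
# so both a moderate and a steep gamma1 start are tried; factor models get a
# third, cascade start: the factor-free double exponential is fitted first
# (cheap, 5 parameters) and its solution expanded with zero offsets.
.deterministic_starts <- function(mf, records, seed) {
  starts <- list(.start_values(mf, gamma1 = -1))
  if (mf$spec$n_exp_terms >= 1)
    starts <- c(starts, list(.start_values(mf, gamma1 = -5)))
  has_factors <- mf$spec$n_exp_terms == 2 &&
    (mf$spec$t2_intercept != "none" || mf$spec$t2_decay != "none" ||
       !is.null(mf$spec$wind))
  if (has_factors) {
    base_fit <- tryCatch(
      fit_decay(records, model_spec(2, "none", "none",
                                    ref_direction = mf$spec$ref_direction),
                n_starts = 4, seed = seed, compute_vcov = FALSE),
      error = function(e) NULL)
    if (!is.null(base_fit)) {
      par <- stats::setNames(numeric(length(mf$terms)), mf$terms)
      par[names(coef(base_fit))] <- coef(base_fit)
      par[["gamma2"]] <- min(par[["gamma2"]], -1e-4)  # keep constrainable
      par[["gamma1"]] <- min(par[["gamma1"]], -1e-4)
      starts <- c(starts, list(par))
    }
  }
  starts
}

.rel_grad <- function(g, theta, nll) {
  max(abs(g) * pmax(abs(theta), 1)) / max(abs(nll), 1)
}

#' Fit the decay model by maximum likelihood
#'
#' Maximizes the grouped binomial likelihood of a [model_spec()] on
#' screening records. The double-exponential surface is nonconvex, so the
#' optimizer runs from `n_starts` seeded starting points (one heuristic
#' start plus randomized perturbations) and keeps the best optimum. With
#' `constraints = TRUE` (default) the reference decay rates are kept
#' negative through a log reparameterization; factor offsets are always
#' unconstrained. The coefficient covariance is the inverse observed
#' information, obtained by central finite differences of the analytic
#' gradient at the optimum (relative step 1e-5).
#'
#' When the two exponential terms are exchangeable (no second-term factors
#' or wind covariate) the terms are relabelled after fitting so that
#' |gamma1| >= |gamma2|: the first term is, by convention, the fast-decay
#' (near-source) term.
#'
#' @param records screening records.
#' @param spec a [model_spec()]; default is the full direction-by-year
#'   double exponential model.
#' @param init optional named starting vector (natural scale).
#' @param constraints keep reference decay rates negative?
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed integer seed controlling the randomized restarts.
#' @param wind wind summary table for wind-covariate specs.
#' @param compute_vcov set `FALSE` to skip the information matrix (used by
#'   bulk model screening).
#' @return an object of class `"pmgf_fit"`: list with `coefficients`
#'   (a [decay_coefficients()] with `vcov`), `loglik`, `k`, `aic`,
#'   `converged`, `n_obs`, `spec`, and a per-start `trace` data.frame.
#' @examples
#' truth <- generator_truth(n_per_cell = 400, seed = 1)
#' rec <- generate_screening(truth)
#' f <- fit_decay(rec, model_spec(2, "none", "none"), n_starts = 2, seed = 1)
#' round(coef(f), 2)
#' @export
fit_decay <- function(records, spec = model_spec(2, "direction:year",
                                                 "direction:year"),
                      init = NULL, constraints = TRUE, n_starts = 8,
                      seed = 1, wind = NULL, compute_vcov = TRUE) {
  stopifnot(inherits(spec, "pmgf_model_spec"), n_starts >= 1)
  records <- as_screening_records(as.data.frame(records))
  if (length(unique(records$distance_m)) < 2 && spec$n_exp_terms > 0)
    stop("distances are all equal; decay terms are not estimable",
         call. = FALSE)
  mf <- .model_frame(records, spec, wind = wind)
  # estimability: full column rank of the stacked second-term designs
  if (spec$n_exp_terms == 2) {
    for (X in list(mf$Xb, mf$Xg))
      if (qr(X)$rank < ncol(X))
        stop("model '", spec$name, "' is not estimable on these data ",
             "(rank-deficient factor coding)", call. = FALSE)
  }
  cidx <- if (constraints) .constrained_idx(mf) else character()

  if (!is.null(init)) {
    missing <- setdiff(mf$terms, names(init))
    if (length(missing))
      stop("init lacks coefficient(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    det_starts <- list(init[mf$terms])
    if (any(det_starts[[1]][cidx] >= 0))
      stop("init decay rates must be negative when constraints are on",
           call. = FALSE)
  } else {
    det_starts <- .deterministic_starts(mf, records, seed)
  }
  det_starts <- lapply(det_starts, .to_theta, cidx = cidx)

  fn <- function(th) .nll_natural(.to_natural(th, cidx), mf)
  gr <- function(th) {
    par <- .to_natural(th, cidx)
    g <- .grad_natural(par, mf)
    g[cidx] <- g[cidx] * par[cidx]       # chain rule d(-exp)/dtheta = gamma
    g
  }

  set.seed(seed)
  starts <- det_starts[seq_len(min(length(det_starts), n_starts))]
  while (length(starts) < n_starts) {
    anchor <- det_starts[[(length(starts) %% length(det_starts)) + 1L]]
    starts <- c(starts, list(anchor + stats::rnorm(length(anchor), sd = 0.5)))
  }

  trace <- data.frame(start = seq_len(n_starts), nll = NA_real_,
                      convergence = NA_integer_, rel_grad = NA_real_,
                      error = NA_character_)
  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[[s]], fn, gr, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) e)
    if (inherits(res, "error")) {
      trace$error[s] <- conditionMessage(res)
      next
    }
    trace$nll[s] <- res$value
    trace$convergence[s] <- res$convergence
    trace$rel_grad[s] <- .rel_grad(gr(res$par), res$par, res$value)
    if (is.finite(res$value) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("all optimizer starts failed:\n",
         paste(unique(stats::na.omit(trace$error)), collapse = "\n"),
         call. = FALSE)

  # Newton polish on the natural scale: BFGS line searches stall once the
  # achievable function decrease drops into round-off, so the last digits of
  # the optimum come from damped Newton steps on the analytic gradient.
  par <- .to_natural(best$par, cidx)
  nll_cur <- best$value
  for (it in 1:25) {
    g <- .grad_natural(par, mf)
    if (.rel_grad(g, par, nll_cur) <= 1e-9) break
    H <- .obs_information(par, mf)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (damp in 1:12) {
      cand <- par - lambda * step
      if (all(cand[cidx] < 0)) {           # stay in the constrained region
        v <- .nll_natural(cand, mf)
        if (is.finite(v) && v <= nll_cur + 1e-9) {
          par <- cand
          nll_cur <- v
          improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  relg <- .rel_grad(.grad_natural(par, mf), par, nll_cur)

  # label-switching: exchangeable terms are ordered fast-decay first
  if (spec$n_exp_terms == 2 && spec$t2_intercept == "none" &&
      spec$t2_decay == "none" && is.null(spec$wind) &&
      abs(par[["gamma1"]]) < abs(par[["gamma2"]])) {
    par[c("beta1", "gamma1", "beta2", "gamma2")] <-
      par[c("beta2", "gamma2", "beta1", "gamma1")]
  }

  vc <- NULL
  if (compute_vcov) {
    H <- .obs_information(par, mf)
    vc <- tryCatch({
      V <- solve(H)
      if (any(!is.finite(V)) || any(diag(V) <= 0)) NULL else V
    }, error = function(e) NULL)
    if (is.null(vc))
      warning("observed information is singular; vcov unavailable",
              call. = FALSE)
  }

  nll <- .nll_natural(par, mf)
  k <- length(par)
  cf <- decay_coefficients(par, spec, directions = mf$directions,
                           years = mf$years, vcov = vc)
  structure(
    list(coefficients = cf, loglik = -nll, k = k, aic = 2 * nll + 2 * k,
         converged = relg <= 1e-8, rel_grad = relg, n_obs = nrow(records),
         spec = spec, trace = trace, wind = wind),
    class = "pmgf_fit")
}

# Observed information: central differences of the analytic gradient,
# relative step 1e-5, symmetrized.
.obs_information <- function(par, mf, rel_step = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k, dimnames = list(names(par), names(par)))
  for (j in seq_len(k)) {
    h <- rel_step * max(abs(par[j]), 1)
    up <- dn <- par
    up[j] <- par[j] + h
    dn[j] <- par[j] - h
    H[, j] <- (.grad_natural(up, mf) - .grad_natural(dn, mf)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.pmgf_fit <- function(x, ...) {
  cat("PMGF decay model fit:", x$spec$name, "\n")
  cat(sprintf("  cells: %d   K: %d   logLik: %.3f   AIC: %.3f\n",
              x$n_obs, x$k, x$loglik, x$aic))
  cat("  converged:", x$converged,
      sprintf("(scaled gradient %.2e)\n", x$rel_grad))
  invisible(x)
}

#' @export
coef.pmgf_fit <- function(object, ...) object$coefficients$coef

#' @export
vcov.pmgf_fit <- function(object, ...) object$coefficients$vcov

#' @export
logLik.pmgf_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
predict.pmgf_fit <- function(object, distance_m, direction = NULL,
                             year = NULL, ...) {
  predict_frequency(object$coefficients, distance_m, direction, year,
                    wind = object$wind)
}

#' Wald coefficient table of a fitted decay model
#'
#' @param object a fitted model from [fit_decay()].
#' @param ... unused.
#' @return data.frame with columns `term`, `estimate`, `std_error`,
#'   `z_value`, `p_value`. Standard errors are Wald (inverse observed
#'   information); z = estimate / SE.
#' @export
summary.pmgf_fit <- function(object, ...) {
  est <- object$coefficients$coef
  vc <- object$coefficients$vcov
  se <- if (is.null(vc)) rep(NA_real_, length(est)) else sqrt(diag(vc))
  z <- est / se
  out <- data.frame(term = names(est), estimate = unname(est),
                    std_error = unname(se), z_value = unname(z),
                    p_value = unname(2 * stats::pnorm(-abs(z))))
  rownames(out) <- NULL
  out
}

# ---- goodness of fit ----------------------------------------------------

#' Pearson chi-squared goodness of fit for grouped binomial data
#'
#' chi^2 = sum_i n_i (y_i - mu_i)^2 / (mu_i (n_i - mu_i)) with fitted counts
#' mu_i = n_i * p_i, on n - k - 1 degrees of freedom (n cells, k fitted
#' parameters). Cells with fitted counts exactly at 0 or n_i carry no
#' Pearson information and are excluded with a warning (df reduced).
#'
#' @param fit a `pmgf_fit` (or `decay_coefficients`, in which case `k` must
#'   be supplied).
#' @param records the screening records the fit is judged against.
#' @param fitted_p optional per-cell fitted probabilities overriding the
#'   model's predictions (used for oracle checks).
#' @param k number of fitted parameters; defaults to the fit's.
#' @return list of class `"pmgf_gof"` with `chisq`, `df`, `dispersion`
#'   (chisq/df), `n_cells`, `n_excluded`.
#' @export
pearson_gof <- function(fit, records, fitted_p = NULL, k = NULL) {
  records <- as_screening_records(as.data.frame(records))
  if (is.null(fitted_p)) {
    cf <- .as_coefficients(fit)
    wind <- if (inherits(fit, "pmgf_fit")) fit$wind
    mf <- .model_frame(records, cf$spec, wind = wind,
                       directions = cf$directions, years = cf$years)
    fitted_p <- stats::plogis(.eta_parts(cf$coef, mf)$eta)
  }
  if (is.null(k)) {
    if (!inherits(fit, "pmgf_fit"))
      stop("supply `k` when `fit` is not a pmgf_fit", call. = FALSE)
    k <- fit$k
  }
  n <- records$n_screened
  y <- records$n_resistant
  mu <- n * fitted_p
  keep <- mu > 0 & mu < n
  n_excl <- sum(!keep)
  if (n_excl > 0)
    warning(sprintf("%d cell(s) with degenerate fitted counts excluded",
                    n_excl), call. = FALSE)
  chisq <- sum(n[keep] * (y[keep] - mu[keep])^2 / (mu[keep] * (n[keep] - mu[keep])))
  df <- sum(keep) - k - 1
  if (df < 1)
    warning("degrees of freedom below 1; dispersion not interpretable",
            call. = FALSE)
  structure(list(chisq = chisq, df = df,
                 dispersion = if (df >= 1) chisq / df else NA_real_,
                 n_cells = sum(keep), n_excluded = n_excl),
            class = "pmgf_gof")
}

#' @export
print.pmgf_gof <- function(x, ...) {
  cat(sprintf("Pearson chi-squared: %.3f on %d df (dispersion %.3f)\n",
              x$chisq, x$df, x$dispersion))
  if (x$n_excluded > 0)
    cat("  cells excluded as degenerate:", x$n_excluded, "\n")
  invisible(x)
}
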