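# Descriptive statistics: gene-flow frequency, flowering synchrony, wind
# rose aggregation and PMGF-wind correlation.

#' Frequency of gene flow
#'
#' The fraction of screened seedlings surviving the discriminating herbicide
#' rate: survivors / screened. The exact ratio is returned; reporting layers
#' round to two decimals.
#'
#' @param n_resistant,n_screened counts (vectorized).
#' @return proportion(s) in \[0, 1\].
#' @examples
#' round(gene_flow_frequency(1546, 2591), 2)  # 0.60
#' @export
gene_flow_frequency <- function(n_resistant, n_screened) {
  if (any(n_screened <= 0))
    stop("frequency undefined where n_screened is 0; exclude such cells",
         call. = FALSE)
  if (any(n_resistant < 0) || any(n_resistant > n_screened))
    stop("need 0 <= n_resistant <= n_screened", call. = FALSE)
  n_resistant / n_screened
}

#' Pool screening counts over directions and summarize by distance
#'
#' Counts are summed over the eight directions FIRST and the ratio taken on
#' the pooled counts (the printed per-distance frequencies of the source
#' study are count ratios, not means of per-direction ratios); a
#' mean-of-ratios alternative is available via `pooling = "mean_ratio"`.
#' By default the first-year 0.1 m cell is excluded, mirroring the study's
#' exclusion of that distance for insufficient detection power.
#'
#' @param records screening records, or any data.frame with columns `year`,
#'   `distance_m`, `n_screened`, `n_resistant` (a `direction` column is
#'   optional -- already-pooled marginals are accepted).
#' @param year optional single year label to restrict to.
#' @param pooling `"counts"` (pooled ratio) or `"mean_ratio"`.
#' @param exclude_cells data.frame of (`year`, `distance_m`) cells to drop
#'   before pooling; `NULL` keeps everything.
#' @return data.frame with columns `year`, `distance_m`, `total_screened`,
#'   `total_resistant`, `frequency`, ordered by year then distance.
#' @examples
#' pooled_frequency_by_distance(published_counts(), year = 2014)
#' @export
pooled_frequency_by_distance <- function(records, year = NULL,
                                         pooling = c("counts", "mean_ratio"),
                                         exclude_cells = data.frame(
                                           year = "2014", distance_m = 0.1)) {
  pooling <- match.arg(pooling)
  df <- as.data.frame(records)
  .require_columns(df, c("year", "distance_m", "n_screened", "n_resistant"),
                   "screening data")
  df$year <- as.character(df$year)
  if (!is.null(year)) df <- df[df$year == as.character(year), , drop = FALSE]
  if (!is.null(exclude_cells) && nrow(exclude_cells))
    df <- df[!(paste(df$year, df$distance_m) %in%
                 paste(as.character(exclude_cells$year),
                       exclude_cells$distance_m)), , drop = FALSE]
  if (nrow(df) == 0) stop("no screening records to pool", call. = FALSE)
  key <- interaction(df$year, df$distance_m, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(
      year = g$year[1], distance_m = g$distance_m[1],
      total_screened = sum(g$n_screened),
      total_resistant = sum(g$n_resistant),
      frequency = if (pooling == "counts")
        gene_flow_frequency(sum(g$n_resistant), sum(g$n_screened))
      else mean(gene_flow_frequency(g$n_resistant, g$n_screened)))
  }))
  out <- out[order(out$year, out$distance_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flowering synchrony between donor and receptor blocks
#'
#' Two published conventions are implemented and must be chosen explicitly:
#' \describe{
#'   \item{`"eq1"`}{percent synchrony, mean over receptor stations of
#'     receptor flowering over donor shed: `(1/n) sum_i A_i/B * 100`,
#'     where `A_i` is the receptor flowering percentage at station i and
#'     `B` the donor pollen-shed percentage.}
#'   \item{`"table1"`}{the inverted ratio form used in the study's
#'     synchrony table: `(1/n) sum_j A/B_j` with `A` the donor shed
#'     percentage and `B_j` the receptor percentages; 1.0 means perfect
#'     synchrony.}
#' }
#' With `cap = TRUE` each station's ratio is capped at 100% (eq1) or 1
#' (table1): a receptor at or above the donor is fully synchronized.
#'
#' @param receptor_pcts receptor flowering percentages (one per station).
#' @param donor_pct donor pollen-shed percentage (scalar).
#' @param convention `"eq1"` or `"table1"`.
#' @param cap cap per-station ratios at full synchrony?
#' @return scalar: percent (eq1) or ratio (table1).
#' @examples
#' flowering_synchrony(c(25, 50, 75, 50), 50, "eq1")     # 100
#' flowering_synchrony(c(50, 50), 50, "table1")          # 1
#' @export
flowering_synchrony <- function(receptor_pcts, donor_pct,
                                convention = c("eq1", "table1"),
                                cap = FALSE) {
  convention <- match.arg(convention)
  if (any(receptor_pcts < 0) || donor_pct < 0)
    stop("percentages must be non-negative", call. = FALSE)
  if (convention == "eq1") {
    if (donor_pct <= 0)
      stop("synchrony undefined: donor percentage is 0", call. = FALSE)
    ratio <- receptor_pcts / donor_pct
    if (cap) ratio <- pmin(ratio, 1)
    mean(ratio) * 100
  } else {
    if (any(receptor_pcts <= 0))
      stop("synchrony undefined: a receptor percentage is 0", call. = FALSE)
    ratio <- donor_pct / receptor_pcts
    if (cap) ratio <- pmin(ratio, 1)
    mean(ratio)
  }
}

#' Direction-by-date synchrony table
#'
#' Applies [flowering_synchrony()] to generated or observed flowering
#' records, per direction and observation date.
#'
#' @param flowering flowering records ([read_flowering()]).
#' @inheritParams flowering_synchrony
#' @return data.frame with columns `direction`, `date`, `value`,
#'   `convention`.
#' @export
synchrony_table <- function(flowering, convention = c("eq1", "table1"),
                            cap = FALSE) {
  convention <- match.arg(convention)
  df <- as.data.frame(flowering)
  donor <- df[df$block_type == "donor", ]
  rec <- df[df$block_type == "receptor", ]
  if (nrow(donor) == 0 || nrow(rec) == 0)
    stop("need both donor and receptor observations", call. = FALSE)
  out <- do.call(rbind, lapply(split(rec, rec$direction), function(g) {
    do.call(rbind, lapply(split(g, g$date), function(gd) {
      b <- donor$pct_shedding[match(gd$date[1], donor$date)]
      if (is.na(b)) return(NULL)
      data.frame(direction = g$direction[1], date = gd$date[1],
                 value = flowering_synchrony(gd$pct_flowering, b,
                                             convention, cap),
                 convention = convention)
    }))
  }))
  out <- out[order(out$direction, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wind rose: 8-sector aggregation of an hourly wind stream
#'
#' Each hour is binned to the compass sector whose centre is nearest its
#' wind-FROM bearing (half-open 45 degree bins centred on 0, 45, ..., 315
#' degrees; a boundary bearing such as 22.5 belongs to the clockwise-next
#' sector, so \[22.5, 67.5) is NE). Reports per sector the frequency (% of
#' observed hours), the mean speed, and the wind run (mean speed times the
#' frequency as a fraction).
#'
#' @param records weather records ([read_weather()]).
#' @return data.frame with columns `sector`, `n_hours`, `frequency_pct`,
#'   `mean_speed_ms`, `wind_run`. Sectors with no hours report frequency 0,
#'   `NA` mean speed and wind run 0.
#' @examples
#' w <- generate_weather(generator_truth(n_per_cell = 10, seed = 3), weeks = 2)
#' wind_rose(w)
#' @export
wind_rose <- function(records) {
  df <- as.data.frame(records)
  if (nrow(df) == 0) stop("empty weather stream", call. = FALSE)
  sector <- SECTORS[floor(((df$wind_dir_deg + 22.5) %% 360) / 45) + 1L]
  n <- as.numeric(table(factor(sector, levels = SECTORS)))
  total <- nrow(df)
  speed <- vapply(SECTORS, function(s) {
    v <- df$wind_speed_ms[sector == s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  freq <- 100 * n / total
  run <- ifelse(n > 0, speed * (n / total), 0)
  data.frame(sector = SECTORS, n_hours = as.integer(n),
             frequency_pct = freq, mean_speed_ms = unname(speed),
             wind_run = unname(run))
}

#' Correlate per-direction gene flow with wind parameters
#'
#' Pearson product-moment correlation (via [stats::cor.test()]) between the
#' eight per-direction gene-flow frequencies at each distance and a wind
#' summary. `mapping = "downwind"` (biologically motivated default) pairs
#' the frequency in arm d with the wind summary of the OPPOSITE sector --
#' wind blowing from the south carries pollen into the north arm;
#' `mapping = "sector"` pairs same-named sectors.
#'
#' @param records screening records (with a `direction` column).
#' @param wind a [wind_rose()] summary.
#' @param parameter wind quantity: `"speed"`, `"frequency"` or `"run"`.
#' @param mapping `"downwind"` or `"sector"`.
#' @param year optional year restriction.
#' @return data.frame with one row per (year, distance): `r`, `p_value`,
#'   `n_pairs`, `degenerate` (TRUE where a vector had zero variance; `r`
#'   is then `NA`, never silently NaN).
#' @export
correlate_pmgf_wind <- function(records, wind,
                                parameter = c("run", "speed", "frequency"),
                                mapping = c("downwind", "sector"),
                                year = NULL) {
  parameter <- match.arg(parameter)
  mapping <- match.arg(mapping)
  df <- as.data.frame(records)
  .require_columns(df, c("year", "direction", "distance_m", "n_screened",
                         "n_resistant"), "screening data")
  df$year <- as.character(df$year)
  if (!is.null(year)) df <- df[df$year == as.character(year), , drop = FALSE]
  col <- switch(parameter, speed = "mean_speed_ms",
                frequency = "frequency_pct", run = "wind_run")
  wsec <- if (mapping == "downwind") OPPOSITE_SECTOR[df$direction]
  else df$direction
  df$wind_value <- wind[[col]][match(wsec, as.character(wind$sector))]
  key <- interaction(df$year, df$distance_m, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    x <- gene_flow_frequency(g$n_resistant, g$n_screened)
    w <- g$wind_value
    ok <- is.finite(x) & is.finite(w)
    degenerate <- sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(w[ok]) == 0
    if (degenerate) {
      r <- p <- NA_real_
    } else {
      ct <- stats::cor.test(x[ok], w[ok], method = "pearson")
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
    data.frame(year = g$year[1], distance_m = g$distance_m[1],
               parameter = parameter, mapping = mapping, r = r, p_value = p,
               n_pairs = sum(ok), degenerate = degenerate)
  }))
  out <- out[order(out$year, out$distance_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}
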