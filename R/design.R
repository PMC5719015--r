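#' Concentric (Nelder wheel) field design
#'
#' Describes the layout of a PMGF field experiment: a circular pollen-donor
#' block in the centre and receptor stations along the eight compass arms at
#' fixed distances from the donor EDGE (not its centre). The default values
#' reproduce the study layout this package was built around: a 5 m donor
#' radius, receptor distances 0.1--35 m on every arm and an additional 50 m
#' station on the ordinal (NE/NW/SE/SW) arms only, six plants per station.
#'
#' @param donor_radius_m radius of the central donor circle, m.
#' @param cardinal_distances_m strictly increasing receptor distances (m)
#'   planted on all eight arms.
#' @param ordinal_extra_m additional distances planted only on the ordinal
#'   arms; may be `numeric(0)`.
#' @param plants_per_station number of receptor plants per station.
#' @return an object of class `"field_design"`.
#' @examples
#' field_design()
#' @export
field_design <- function(donor_radius_m = 5,
                         cardinal_distances_m = c(0.1, 0.5, 1, 2, 4, 10, 15, 25, 35),
                         ordinal_extra_m = 50,
                         plants_per_station = 6) {
  stopifnot(is.numeric(donor_radius_m), length(donor_radius_m) == 1L,
            donor_radius_m > 0)
  d <- as.numeric(cardinal_distances_m)
  if (length(d) == 0 || any(d <= 0) || any(diff(d) <= 0))
    stop("`cardinal_distances_m` must be positive and strictly increasing")
  e <- as.numeric(ordinal_extra_m)
  if (any(e <= 0)) stop("`ordinal_extra_m` must be positive")
  if (length(e) && min(e) <= max(d))
    stop("`ordinal_extra_m` must exceed the largest cardinal distance")
  stopifnot(plants_per_station >= 1)
  structure(
    list(donor_radius_m = donor_radius_m,
         cardinal_distances_m = d,
         ordinal_extra_m = e,
         plants_per_station = as.integer(plants_per_station)),
    class = "field_design"
  )
}

#' @export
print.field_design <- function(x, ...) {
  cat("Concentric PMGF field design\n")
  cat("  donor radius:       ", x$donor_radius_m, "m\n")
  cat("  all-arm distances:  ", paste(x$cardinal_distances_m, collapse = ", "),
      "m\n")
  if (length(x$ordinal_extra_m))
    cat("  ordinal-only extra: ", paste(x$ordinal_extra_m, collapse = ", "),
        "m\n")
  cat("  plants per station: ", x$plants_per_station, "\n")
  invisible(x)
}

#' Enumerate the (year, direction, distance) cells of a design
#'
#' @param design a [field_design()].
#' @param years character or numeric vector of study-year labels.
#' @return data.frame with columns `year`, `direction`, `distance_m`, one row
#'   per screening cell, ordered by year, direction (N, NE, E, SE, S, SW, W,
#'   NW), distance.
#' @examples
#' nrow(design_cells(field_design(), years = c(2014, 2015)))
#' @export
design_cells <- function(design = field_design(), years = c(2014, 2015)) {
  stopifnot(inherits(design, "field_design"))
  cardinal <- c("N", "E", "S", "W")
  out <- do.call(rbind, lapply(as.character(years), function(yr) {
    do.call(rbind, lapply(SECTORS, function(dir) {
      d <- design$cardinal_distances_m
      if (!(dir %in% cardinal)) d <- c(d, design$ordinal_extra_m)
      data.frame(year = yr, direction = dir, distance_m = d,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Packaged marginal screening counts by distance
#'
#' Per-year totals of receptor seedlings screened and found resistant at each
#' distance, pooled over the eight directions, as printed in the source
#' study's summary table (2014: nine distances 0.5--50 m; 2015: ten distances
#' 0.1--50 m). `frequency_printed` and `power_printed` carry the published
#' rounded values for cross-checking; all package computations use the raw
#' counts.
#'
#' @return data.frame with columns `year`, `distance_m`, `n_screened`,
#'   `n_resistant`, `frequency_printed`, `power_printed`.
#' @examples
#' tab <- published_counts()
#' sum(tab$n_screened)   # 100938
#' @export
published_counts <- function() {
  path <- system.file("extdata", "screening_counts_by_distance.csv", package = "pmgflow",
                      mustWork = TRUE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(year = "character"))
  out
}

#' Packaged double-exponential-decay coefficient table
#'
#' The published coefficient estimates (with standard errors and Wald tests)
#' of the best-supported dispersal model: a double exponential decay on the
#' logit of gene-flow frequency with the second term's intercept and decay
#' rate coded by direction, year and their interaction (treatment contrasts;
#' reference level East / 2014). Values are as printed (2 decimals), so
#' downstream quantities derived from them are approximate reference values,
#' not reproductions of the study's full-precision fit.
#'
#' @return data.frame with columns `term`, `estimate`, `std_error`,
#'   `z_value`, `p_value`.
#' @examples
#' head(published_coefficients())
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "decay_model_coefficients.csv",
                      package = "pmgflow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
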