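# End-to-end orchestration: (simulate ->) summarize -> select -> fit ->
# predict -> report, with a manifest sufficient to re-execute the run.

#' Configuration for [run_pipeline()]
#'
#' Either point the three `*_csv` paths at existing input files, or leave
#' them `NULL` and supply `truth` (a [generator_truth()]) to simulate them.
#'
#' @param out_dir output directory (created if needed).
#' @param screening_csv,weather_csv,flowering_csv input CSV paths, or
#'   `NULL` to simulate.
#' @param truth [generator_truth()] used when inputs are simulated.
#' @param seed root seed recorded in every output and used for model
#'   selection and bootstrap stages.
#' @param specs candidate list for the selection stage (`NULL` for the
#'   default [build_candidate_set()]); set `do_selection = FALSE` to fit
#'   only `final_spec`.
#' @param do_selection run the AIC selection stage?
#' @param final_spec spec fitted for inference when selection is off.
#' @param n_starts optimizer starts per fit.
#' @param n_boot bootstrap draws for reduction intervals.
#' @param rounding decimals for the rounded companion columns in report
#'   tables (full-precision columns are always written).
#' @param overwrite allow writing into a non-empty `out_dir`?
#' @param weather_weeks,weather_start simulated weather stream extent.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            screening_csv = NULL, weather_csv = NULL,
                            flowering_csv = NULL, truth = NULL, seed = 1,
                            specs = NULL, do_selection = TRUE,
                            final_spec = model_spec(2, "direction:year",
                                                    "direction:year"),
                            n_starts = 8, n_boot = 1000,
                            rounding = 2, overwrite = FALSE,
                            weather_weeks = 6, weather_start = "2014-07-25") {
  if (is.null(screening_csv) && is.null(truth))
    stop("either supply input CSVs or a generator truth", call. = FALSE)
  structure(
    list(out_dir = out_dir, screening_csv = screening_csv,
         weather_csv = weather_csv, flowering_csv = flowering_csv,
         truth = truth, seed = as.integer(seed), specs = specs,
         do_selection = isTRUE(do_selection), final_spec = final_spec,
         n_starts = n_starts, n_boot = n_boot,
         rounding = rounding, overwrite = isTRUE(overwrite),
         weather_weeks = weather_weeks, weather_start = weather_start),
    class = "pipeline_config")
}

.pipeline_write <- function(df, dir, name, rounding = NULL) {
  if (!is.null(rounding)) {
    num <- vapply(df, is.numeric, logical(1))
    for (col in names(df)[num])
      df[[paste0(col, "_rounded")]] <- round(df[[col]], rounding)
  }
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full PMGF analysis pipeline
#'
#' Stages: load or simulate the three inputs; descriptive summaries
#' (frequency-by-distance, synchrony-by-date, wind rose, PMGF-wind
#' correlations); AIC model selection (optional); final-model fit with
#' Wald coefficient table and Pearson goodness of fit; O50/O90 dispersal
#' table; and a JSON manifest recording config, seeds and package version
#' so the run can be re-executed. Reruns with an identical config are
#' byte-identical. Any stage failure raises an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage's in-memory result and the
#'   written file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  existing <- list.files(config$out_dir)
  if (length(existing) && !config$overwrite)
    stop("pipeline[setup]: output directory not empty; set overwrite = TRUE",
         call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline[%s]: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  paths <- list()

  inputs <- stage("inputs", {
    if (!is.null(config$screening_csv)) {
      list(screening = read_screening(config$screening_csv),
           weather = if (!is.null(config$weather_csv))
             read_weather(config$weather_csv),
           flowering = if (!is.null(config$flowering_csv))
             read_flowering(config$flowering_csv))
    } else {
      tr <- config$truth
      scr <- generate_screening(tr)
      wx <- generate_weather(tr, start = config$weather_start,
                             weeks = config$weather_weeks)
      fl <- generate_flowering(tr$design, seed = tr$seed,
                               start = config$weather_start)
      paths$screening <- write_screening(
        scr, file.path(config$out_dir, "input_screening.csv"))
      paths$weather <- write_weather(
        wx, file.path(config$out_dir, "input_weather.csv"))
      paths$flowering <- write_flowering(
        fl, file.path(config$out_dir, "input_flowering.csv"))
      list(screening = scr, weather = wx, flowering = fl)
    }
  })

  summaries <- stage("summaries", {
    freq <- pooled_frequency_by_distance(inputs$screening,
                                         exclude_cells = NULL)
    paths$frequency <- .pipeline_write(freq, config$out_dir,
                                        "frequency_by_distance.csv",
                                        config$rounding)
    rose <- synch <- corr <- NULL
    if (!is.null(inputs$weather) && nrow(inputs$weather)) {
      rose <- wind_rose(inputs$weather)
      paths$wind_rose <- .pipeline_write(rose, config$out_dir,
                                          "wind_rose.csv", config$rounding)
      corr <- do.call(rbind, lapply(c("speed", "frequency", "run"),
                                    function(par)
        correlate_pmgf_wind(inputs$screening, rose, par)))
      paths$correlation <- .pipeline_write(corr, config$out_dir,
                                            "pmgf_wind_correlation.csv",
                                            config$rounding)
    }
    if (!is.null(inputs$flowering)) {
      synch <- synchrony_table(inputs$flowering, convention = "table1")
      paths$synchrony <- .pipeline_write(synch, config$out_dir,
                                          "synchrony_by_date.csv",
                                          config$rounding)
    }
    list(frequency = freq, wind_rose = rose, synchrony = synch,
         correlation = corr)
  })

  selection <- NULL
  if (config$do_selection) {
    selection <- stage("selection", {
      specs <- config$specs
      if (is.null(specs))
        specs <- build_candidate_set(
          include_wind = !is.null(summaries$wind_rose))
      tab <- select_best(inputs$screening, specs, seed = config$seed,
                         wind = summaries$wind_rose,
                         n_starts = config$n_starts)
      paths$selection <- .pipeline_write(as.data.frame(tab),
                                          config$out_dir,
                                          "model_selection.csv")
      tab
    })
  }

  fit <- stage("fit", {
    spec <- if (!is.null(selection))
      attr(selection, "fits")[[selection$model[1]]]$spec
    else config$final_spec
    f <- fit_decay(inputs$screening, spec, seed = config$seed,
                   n_starts = config$n_starts,
                   wind = summaries$wind_rose)
    paths$coefficients <- .pipeline_write(summary(f), config$out_dir,
                                           "coefficient_table.csv")
    gof <- pearson_gof(f, inputs$screening)
    paths$gof <- .pipeline_write(
      data.frame(chisq = gof$chisq, df = gof$df,
                 dispersion = gof$dispersion, n_cells = gof$n_cells),
      config$out_dir, "goodness_of_fit.csv")
    f
  })

  reductions <- stage("reductions", {
    refs <- vapply(split(inputs$screening$distance_m,
                         inputs$screening$year), min, numeric(1))
    tab <- reduction_table(fit,
                           reference_distance_m = refs[fit$coefficients$years],
                           n_boot = config$n_boot, seed = config$seed)
    paths$reductions <- .pipeline_write(tab, config$out_dir,
                                         "reduction_distances.csv",
                                         config$rounding)
    tab
  })

  stage("manifest", {
    manifest <- list(
      package = "pmgflow",
      version = as.character(utils::packageVersion("pmgflow")),
      seed = config$seed,
      simulated = is.null(config$screening_csv),
      truth_seed = if (!is.null(config$truth)) config$truth$seed,
      final_model = fit$spec$name,
      n_cells = fit$n_obs,
      aic = fit$aic,
      outputs = lapply(paths, basename))   # relative to out_dir
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(config$out_dir, "manifest.json"))
  })

  invisible(list(inputs = inputs, summaries = summaries,
                 selection = selection, fit = fit, reductions = reductions,
                 paths = paths))
}
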