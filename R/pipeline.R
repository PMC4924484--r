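# Pipeline orchestration: one entry point dispatching the analysis stages
# from a serializable run configuration, so a full run is reproducible from
# its config alone.

#' Construct a run configuration
#'
#' @param mode One of `"simulate"`, `"fit-reoxidation"`, `"fit-blue"`,
#'   `"fit-green"`, `"invivo-blue"`, `"invivo-green"`, `"report"`.
#' @param input Input path (spectra or readout CSV; for `"report"` a
#'   directory of per-fit JSON files). Not used by `"simulate"`.
#' @param out Output path prefix (files get extensions appended).
#' @param receptor `"cry1"` or `"cry2"`.
#' @param experiment For `"simulate"`: which design to emulate
#'   (`"reoxidation"`, `"blue_dose"`, `"green_dose"`, `"invivo_blue"`,
#'   `"invivo_green"`).
#' @param eps_ox_450 Extinction at 450 nm (mol^-1 m^2); default the
#'   receptor's in vitro value.
#' @param k1b,k2b Reoxidation rates (s^-1) where the stage needs them.
#' @param k1 Blue-driven rate for green-light stages (s^-1).
#' @param t_illum Illumination time (s).
#' @param exposure_mode `"steady_state"` or `"finite_t"` (in vivo stages).
#' @param seed Integer seed for simulation noise.
#' @param noise_sd Absorbance or readout noise for `"simulate"`.
#' @param species Which concentration feeds reoxidation fits.
#' @param anchors Optional `c(dark, saturated)` readout anchors (in vivo).
#' @param condition Condition label for report rows.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(mode, input = NULL, out = "crycycle_run",
                       receptor = "cry2", experiment = "blue_dose",
                       eps_ox_450 = NULL, k1b = NULL, k2b = 0.011,
                       k1 = NULL, t_illum = 20,
                       exposure_mode = "finite_t", seed = 1L,
                       noise_sd = 0, species = "fadh_rad",
                       anchors = NULL, condition = NULL) {
  mode <- match.arg(mode, c("simulate", "fit-reoxidation", "fit-blue",
                            "fit-green", "invivo-blue", "invivo-green",
                            "report"))
  receptor <- match.arg(receptor, c("cry1", "cry2"))
  if (is.null(eps_ox_450)) eps_ox_450 <- cry_extinction(receptor)
  if (is.null(condition)) condition <- paste(receptor, mode)
  structure(list(mode = mode, input = input, out = out,
                 receptor = receptor, experiment = experiment,
                 eps_ox_450 = eps_ox_450, k1b = k1b, k2b = k2b, k1 = k1,
                 t_illum = t_illum, exposure_mode = exposure_mode,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 species = species, anchors = anchors,
                 condition = condition),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML config path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

pipeline_log <- function(...) message("[crycycle] ", ...)

series_times_by_condition <- function(series, cond) {
  keep <- vapply(series, function(r) r$condition == cond, logical(1))
  series[keep]
}

#' Run an analysis pipeline stage
#'
#' Executes the stage named by `config$mode`, writes its outputs (report
#' CSV/JSON, or simulated data files), and returns the results invisibly.
#' Input validation failures raise errors before any output is written.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return The stage result, invisibly: a report data.frame for fitting
#'   stages, output paths for `"simulate"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  pipeline_log("mode=", config$mode, " receptor=", config$receptor,
               " seed=", config$seed)
  switch(config$mode,
         "simulate" = pipeline_simulate(config),
         "fit-reoxidation" = pipeline_fit_reoxidation(config),
         "fit-blue" = pipeline_fit_blue(config),
         "fit-green" = pipeline_fit_green(config),
         "invivo-blue" = pipeline_invivo(config, "blue"),
         "invivo-green" = pipeline_invivo(config, "green"),
         "report" = pipeline_report(config))
}

pipeline_simulate <- function(config) {
  sc <- synthetic_config(
    eps = extinction_set(config$eps_ox_450),
    k1b_true = if (is.null(config$k1b)) 0.003 else config$k1b,
    k2b_true = config$k2b,
    noise_sd = config$noise_sd, seed = config$seed,
    t_illum = config$t_illum)
  if (config$experiment %in% c("reoxidation", "blue_dose", "green_dose")) {
    series <- switch(config$experiment,
                     reoxidation = generate_reoxidation_series(sc),
                     blue_dose = generate_blue_dose_series(sc),
                     green_dose = generate_green_dose_series(sc))
    path <- paste0(config$out, ".csv")
    write_spectra_csv(series, path)
    truth_path <- paste0(config$out, ".truth.json")
    jsonlite::write_json(attr(series, "truth"), truth_path,
                         auto_unbox = TRUE, digits = NA)
    pipeline_log("wrote ", path, " and ", truth_path)
    invisible(c(data = path, truth = truth_path))
  } else {
    light <- if (config$experiment == "invivo_green") "green" else "blue"
    sigma_true <- if (light == "blue") 4.8e-4 else 3e-5
    series <- generate_invivo_readouts(
      fluences = if (light == "blue") c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10)
                 else c(0, 10, 25, 50, 100, 250, 500),
      sigma_true = sigma_true, receptor = config$receptor,
      exposure_mode = config$exposure_mode, light = light,
      k1 = config$k1, t_illum = config$t_illum,
      noise_sd = config$noise_sd, seed = config$seed)
    truth <- attr(series, "truth")
    path <- paste0(config$out, ".csv")
    write_readout_csv(series, path,
                      extra = list(exposure_mode = config$exposure_mode,
                                   t_illum = config$t_illum,
                                   readout_dark = truth$readout_dark,
                                   readout_saturated = truth$readout_saturated))
    truth_path <- paste0(config$out, ".truth.json")
    jsonlite::write_json(truth[setdiff(names(truth), "fadh")], truth_path,
                         auto_unbox = TRUE, digits = NA)
    pipeline_log("wrote ", path, " and ", truth_path)
    invisible(c(data = path, truth = truth_path))
  }
}

normalized_series <- function(path) {
  series <- read_spectra_csv(path)
  dark_i <- which(vapply(series, function(r) r$condition == "dark_initial",
                         logical(1)))
  if (!length(dark_i))
    stop("no dark_initial record in ", path, call. = FALSE)
  normalize_to_dark(series, series[[dark_i[1]]])
}

pipeline_fit_reoxidation <- function(config) {
  series <- normalized_series(config$input)
  recs <- series_times_by_condition(series, "dark_recovery")
  if (!length(recs)) stop("no dark_recovery records", call. = FALSE)
  conc <- series_concentrations(recs)
  fit <- fit_reoxidation(conc$time, conc[[config$species]],
                         species = config$species)
  pipeline_log("k1b=", signif(fit$k1b, 4), " s^-1, half-life=",
               round(fit$half_life), " s, R2=", signif(fit$r_squared, 3))
  report <- report_row(config$condition, reox = fit)
  write_report(report, config$out)
  invisible(report)
}

pipeline_fit_blue <- function(config) {
  if (is.null(config$k1b))
    stop("fit-blue needs k1b (from a reoxidation fit)", call. = FALSE)
  series <- normalized_series(config$input)
  recs <- series_times_by_condition(series, "illuminated_blue")
  if (!length(recs)) stop("no illuminated_blue records", call. = FALSE)
  conc <- series_concentrations(recs)
  fluence <- vapply(recs, function(r) r$fluence_blue, numeric(1))
  t_illum <- recs[[1]]$time
  k1 <- vapply(seq_along(recs), function(i) {
    if (fluence[i] == 0) return(0)
    obs <- if (config$species == "fadh_rad") conc$fadh_rad[i]
           else conc$fad_ox[i]
    infer_k1(obs, config$species, t_illum, config$k1b)
  }, numeric(1))
  fit <- fit_cross_section(fluence, k1)
  res <- cross_section_result(fit, config$eps_ox_450, "ox_to_radical",
                              config$species)
  pipeline_log("sigma1=", signif(res$sigma, 4), " umol^-1 m^2, phi1=",
               signif(res$phi, 3))
  report <- report_row(config$condition, blue = res)
  write_report(report, config$out)
  invisible(report)
}

pipeline_fit_green <- function(config) {
  if (is.null(config$k1))
    stop("fit-green needs k1 (from the blue-light stage)", call. = FALSE)
  series <- normalized_series(config$input)
  recs <- series_times_by_condition(series, "illuminated_blue_green")
  if (!length(recs)) stop("no illuminated_blue_green records", call. = FALSE)
  conc <- series_concentrations(recs)
  fluence <- vapply(recs, function(r) r$fluence_green, numeric(1))
  t_illum <- recs[[1]]$time
  k1b <- if (is.null(config$k1b)) 0 else config$k1b
  k2b <- if (k1b == 0) 0 else config$k2b
  k2 <- vapply(seq_along(recs), function(i)
    infer_k2(conc$fadh_rad[i], t_illum, config$k1, k1b, k2b),
    numeric(1))
  fit <- fit_cross_section(fluence, k2)
  res <- cross_section_result(fit, config$eps_ox_450 / 2,
                              "radical_to_reduced")
  pipeline_log("sigma2=", signif(res$sigma, 4), " umol^-1 m^2, phi2=",
               signif(res$phi, 3))
  report <- report_row(config$condition, green = res)
  write_report(report, config$out)
  invisible(report)
}

pipeline_invivo <- function(config, light) {
  series <- read_readout_csv(config$input)
  meta <- attr(series, "meta")
  anchors <- config$anchors
  if (is.null(anchors) && !is.null(meta$readout_dark))
    anchors <- c(meta$readout_dark, meta$readout_saturated)
  exposure_mode <- if (!is.null(meta$exposure_mode)) meta$exposure_mode
                   else config$exposure_mode
  t_illum <- if (!is.null(meta$t_illum)) meta$t_illum else config$t_illum
  rates <- literature_rates(k2b = config$k2b)
  res <- if (light == "blue") {
    invivo_blue_quantum_yield(
      series, rates = rates, eps = config$eps_ox_450,
      exposure_mode = exposure_mode, t_illum = t_illum,
      readout_dark = anchors[1], readout_saturated = anchors[2])
  } else {
    if (is.null(config$k1))
      stop("invivo-green needs k1 from the blue stage", call. = FALSE)
    invivo_green_quantum_yield(
      series, k1 = config$k1, rates = rates,
      eps2 = config$eps_ox_450 / 2,
      exposure_mode = exposure_mode, t_illum = t_illum,
      readout_dark = anchors[1], readout_saturated = anchors[2])
  }
  pipeline_log("sigma=", signif(res$sigma, 4), " umol^-1 m^2, phi=",
               signif(res$phi, 3))
  report <- if (light == "blue") report_row(config$condition, blue = res)
            else report_row(config$condition, green = res)
  write_report(report, config$out)
  invisible(report)
}

pipeline_report <- function(config) {
  if (is.null(config$input) || !dir.exists(config$input))
    stop("report mode needs an input directory of report JSON files",
         call. = FALSE)
  files <- list.files(config$input, pattern = "\\.json$",
                      full.names = TRUE)
  files <- files[!grepl("truth", files)]
  if (!length(files)) stop("no report JSON files found", call. = FALSE)
  rows <- lapply(files, function(f)
    jsonlite::fromJSON(f, simplifyDataFrame = TRUE))
  report <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(names(rows[[1]]), names(r))] <- NA
    r[names(rows[[1]])]
  }))
  write_report(report, config$out)
  pipeline_log("combined ", length(files), " reports")
  invisible(report)
}
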