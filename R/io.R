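# File round-tripping: wide-dialect spectra CSV with a YAML metadata
# sidecar, readout CSV, and the results report (CSV + JSON). Numeric values
# are written with 17 significant digits so read/write round trips are
# bit-exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".meta.yml")

#' Write a spectral series to CSV (+ YAML metadata sidecar)
#'
#' Wide dialect: first column `wavelength_nm`, one column `t=<seconds>` per
#' record. All records must share one wavelength grid. Per-record metadata
#' (condition, fluence rates) goes to `<path minus .csv>.meta.yml`.
#'
#' @param series List of [spectrum_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(series, path) {
  stopifnot(length(series) >= 1L)
  wl <- series[[1]]$wavelengths
  for (rec in series)
    if (!identical(rec$wavelengths, wl))
      stop("all records must share one wavelength grid", call. = FALSE)
  cols <- vapply(series, function(r) paste0("t=", r$time), character(1))
  header <- paste(c("wavelength_nm", cols), collapse = ",")
  body <- vapply(seq_along(wl), function(i) {
    paste(c(fmt_num(wl[i]),
            vapply(series, function(r) fmt_num(r$absorbance[i]),
                   character(1))),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  meta <- lapply(series, function(r)
    list(time = r$time, condition = r$condition,
         fluence_blue = r$fluence_blue, fluence_green = r$fluence_green))
  yaml::write_yaml(list(records = meta), sidecar_path(path))
  invisible(path)
}

#' Read a spectral series written by [write_spectra_csv()]
#'
#' @param path CSV path; the `.meta.yml` sidecar must sit next to it.
#' @return List of [spectrum_record()]s.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- yaml::read_yaml(meta_path)$records
  if (length(meta) != ncol(df) - 1L)
    stop("metadata does not match spectra columns", call. = FALSE)
  lapply(seq_along(meta), function(i) {
    m <- meta[[i]]
    spectrum_record(df$wavelength_nm, df[[i + 1L]], time = m$time,
                    condition = m$condition,
                    fluence_blue = m$fluence_blue,
                    fluence_green = m$fluence_green)
  })
}

#' Write an in vivo readout series to CSV (+ YAML metadata sidecar)
#'
#' Columns: `fluence_umol_m2_s`, `readout`, `stderr`. Metadata (receptor,
#' readout kind, blue co-fluence, and optional anchors) goes to the sidecar.
#'
#' @param series A [bio_readout_series()].
#' @param path Output CSV path.
#' @param extra Optional named list merged into the sidecar (e.g. anchors,
#'   exposure mode).
#' @return `path`, invisibly.
#' @export
write_readout_csv <- function(series, path, extra = list()) {
  stopifnot(inherits(series, "bio_readout_series"))
  header <- "fluence_umol_m2_s,readout,stderr"
  body <- vapply(seq_along(series$fluence), function(i)
    paste(fmt_num(c(series$fluence[i], series$readout[i],
                    series$stderr[i])), collapse = ","),
    character(1))
  writeLines(c(header, body), path)
  meta <- c(list(readout_kind = series$readout_kind,
                 receptor = series$receptor,
                 co_fluence_blue = series$co_fluence_blue), extra)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read an in vivo readout series written by [write_readout_csv()]
#'
#' @param path CSV path with `.meta.yml` sidecar.
#' @return A [bio_readout_series()]; sidecar extras are attached as
#'   attribute `"meta"`.
#' @export
read_readout_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  df <- utils::read.csv(path)
  meta <- yaml::read_yaml(meta_path)
  series <- bio_readout_series(df$fluence_umol_m2_s, df$readout,
                               stderr = df$stderr,
                               readout_kind = meta$readout_kind,
                               receptor = meta$receptor,
                               co_fluence_blue = meta$co_fluence_blue)
  attr(series, "meta") <- meta
  series
}

#' Assemble a photocycle summary report
#'
#' One row per condition in the shape of the study's summary table:
#' condition, half-life, cross sections (mol^-1 m^2), quantum yields, plus
#' per-fit diagnostics. Numeric columns carry full precision; the display
#' columns round phi to 3 significant digits and tau to whole seconds.
#'
#' @param condition Condition label.
#' @param reox A `"reoxidation_fit"` (or NULL).
#' @param blue A `"cross_section_result"` for the blue transition (or NULL).
#' @param green A `"cross_section_result"` for the green transition (or
#'   NULL).
#' @return A one-row data.frame.
#' @export
report_row <- function(condition, reox = NULL, blue = NULL, green = NULL) {
  row <- data.frame(
    condition = condition,
    tau_half_s = if (!is.null(reox)) reox$half_life else NA_real_,
    sigma1_mol_m2 = if (!is.null(blue)) blue$sigma * 1e6 else NA_real_,
    sigma2_mol_m2 = if (!is.null(green)) green$sigma * 1e6 else NA_real_,
    phi1 = if (!is.null(blue)) blue$phi else NA_real_,
    phi2 = if (!is.null(green)) green$phi else NA_real_,
    r2_reox = if (!is.null(reox)) reox$r_squared else NA_real_,
    r2_blue = if (!is.null(blue)) blue$r_squared else NA_real_,
    r2_green = if (!is.null(green)) green$r_squared else NA_real_,
    n_reox = if (!is.null(reox)) reox$n_points else NA_integer_,
    species_reox = if (!is.null(reox)) reox$species_fitted else NA_character_)
  row$tau_half_display <- round(row$tau_half_s)
  row$phi1_display <- signif(row$phi1, 3)
  row$phi2_display <- signif(row$phi2, 3)
  row
}

#' Write a report (CSV and JSON)
#'
#' @param report Data frame of [report_row()]s.
#' @param path Output path without extension (writes `<path>.csv` and
#'   `<path>.json`).
#' @return Paths, invisibly.
#' @export
write_report <- function(report, path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}
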