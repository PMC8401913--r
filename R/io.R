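# Plain-text I/O: profile/plate/chromatogram CSV schemas and the flat
# key=value run configuration format. No vendor MS formats.

profile_cols <- c("subject_id", "route", "dose_mg_per_kg", "body_weight_kg",
                  "time_min", "conc_ng_per_ml", "blq")
plate_cols <- c("role", "nominal_ng_per_ml", "analyte_response",
                "is_response", "run_id", "condition")
chrom_cols <- c("time_min", "intensity", "channel_q1_mz", "channel_q3_mz")

require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    pk_stop(sprintf("%s is missing columns: %s", what,
                    paste(missing, collapse = ", ")),
            "pkassay_io_error")
  df
}

#' Read and write concentration-time profile CSV files
#'
#' The profile schema has one row per (subject, time point):
#' `subject_id, route, dose_mg_per_kg, body_weight_kg, time_min,
#' conc_ng_per_ml, blq` (blq coded 0/1).
#'
#' @param profiles a list of [conc_profile] objects.
#' @param path file path.
#' @return `read_profiles()` returns a list of [conc_profile];
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id, route = p$route,
               dose_mg_per_kg = p$dose_per_kg,
               body_weight_kg = p$body_weight,
               time_min = p$time, conc_ng_per_ml = p$conc,
               blq = as.integer(p$blq), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  if (!file.exists(path))
    pk_stop(sprintf("profile CSV not found: %s", path), "pkassay_io_error")
  df <- require_cols(utils::read.csv(path, stringsAsFactors = FALSE),
                     profile_cols, "profile CSV")
  lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$time_min), ]
    conc_profile(d$subject_id[1], d$route[1], d$dose_mg_per_kg[1],
                 d$body_weight_kg[1], d$time_min, d$conc_ng_per_ml,
                 as.logical(d$blq))
  })
}

#' Read and write plate CSV files
#'
#' The plate schema: `role` (blank | zero | cal | qc | stability |
#' dilution), `nominal_ng_per_ml`, `analyte_response`, `is_response`,
#' `run_id`, `condition`.
#'
#' @param plate a plate data.frame.
#' @param path file path.
#' @return `read_plate()` returns the plate data.frame.
#' @export
write_plate <- function(plate, path) {
  require_cols(plate, plate_cols, "plate data.frame")
  utils::write.csv(plate[, plate_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate
#' @export
read_plate <- function(path) {
  if (!file.exists(path))
    pk_stop(sprintf("plate CSV not found: %s", path), "pkassay_io_error")
  require_cols(utils::read.csv(path, stringsAsFactors = FALSE),
               plate_cols, "plate CSV")
}

#' Read and write chromatogram CSV files
#'
#' Schema: `time_min, intensity, channel_q1_mz, channel_q3_mz`.
#'
#' @param trace a [chromatogram_trace].
#' @param path file path.
#' @return `read_chromatogram()` returns a [chromatogram_trace].
#' @export
write_chromatogram <- function(trace, path) {
  df <- data.frame(time_min = trace$times, intensity = trace$intensities,
                   channel_q1_mz = trace$channel[1],
                   channel_q3_mz = trace$channel[2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  if (!file.exists(path))
    pk_stop(sprintf("chromatogram CSV not found: %s", path), "pkassay_io_error")
  df <- require_cols(utils::read.csv(path), chrom_cols, "chromatogram CSV")
  chromatogram_trace(df$time_min, df$intensity,
                     c(df$channel_q1_mz[1], df$channel_q3_mz[1]))
}

#' Read and write flat key=value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' parsed as numbers when possible, comma-separated values become
#' numeric vectors. A `seed` key is mandatory.
#'
#' @param path file path.
#' @param config named list to write.
#' @param require_seed error if the file has no `seed` key.
#' @return `read_config()` returns a named list.
#' @export
read_config <- function(path, require_seed = TRUE) {
  if (!file.exists(path))
    pk_stop(sprintf("config file not found: %s", path), "pkassay_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      pk_stop(sprintf("malformed config line (expected key = value): '%s'", ln),
              "pkassay_config_error")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else val
  }
  if (require_seed && is.null(cfg$seed))
    pk_stop("config must set `seed`", "pkassay_config_error")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
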