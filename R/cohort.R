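#' Read a clinical cohort table from CSV
#'
#' Expected columns: `patient_id`, `updrs3_pre`, `updrs3_post` (mandatory)
#' and `ledd_pre`, `ledd_post`, `followup_years`, `cohort_label`, `arm`
#' (optional). Optional columns that are absent, and unparseable numeric
#' cells such as `"N/A"`, become `NA` -- never silent zeros.
#'
#' @param path CSV file with a header row.
#' @return data.frame of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "N/A", "n/a", ""))
  as_cohort_table(df)
}

#' Coerce a data.frame to a cohort table
#'
#' @param df data.frame with at least `patient_id`, `updrs3_pre`,
#'   `updrs3_post`.
#' @return data.frame of class `cohort_table` with all schema columns
#'   present (missing optionals filled with `NA`) and numeric typing.
#' @export
as_cohort_table <- function(df) {
  mandatory <- c("patient_id", "updrs3_pre", "updrs3_post")
  optional <- c("ledd_pre", "ledd_post", "followup_years",
                "cohort_label", "arm")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("cohort table schema error: missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (col in optional)
    if (!col %in% names(df)) df[[col]] <- NA
  num_cols <- c("updrs3_pre", "updrs3_post", "ledd_pre", "ledd_post",
                "followup_years")
  for (col in num_cols) {
    v <- df[[col]]
    if (is.character(v)) v[v %in% c("N/A", "n/a", "")] <- NA
    df[[col]] <- suppressWarnings(as.numeric(v))
  }
  df$patient_id <- as.character(df$patient_id)
  bad <- !is.na(df$updrs3_pre) & df$updrs3_pre < 0 |
         !is.na(df$updrs3_post) & df$updrs3_post < 0
  if (any(bad)) stop("UPDRS-III values must be >= 0")
  if (any(!is.na(df$ledd_pre) & df$ledd_pre < 0) ||
      any(!is.na(df$ledd_post) & df$ledd_post < 0))
    stop("LEDD values must be >= 0")
  df <- df[c(mandatory, optional)]
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table as CSV
#'
#' @param cohort `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Construct a single electrode stimulation record
#'
#' Describes the active contact and stimulation parameters actually used
#' for chronic stimulation in one hemisphere of one patient.
#'
#' @param patient_id character id.
#' @param contact_mm length-3 template-space mm coordinate of the active
#'   contact.
#' @param amplitude stimulation amplitude (> 0).
#' @param amplitude_unit `"V"` (voltage-controlled) or `"mA"`
#'   (current-controlled).
#' @param pulse_width_us pulse width in microseconds (> 0).
#' @param frequency_hz stimulation frequency in Hz (> 0).
#' @param hemisphere `"left"` or `"right"`.
#' @return one-row data.frame of class `electrode_stims`.
#' @export
electrode_stim <- function(patient_id, contact_mm, amplitude,
                           amplitude_unit = "V", pulse_width_us = 60,
                           frequency_hz = 130, hemisphere = "right") {
  stopifnot(length(contact_mm) == 3L)
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (pulse_width_us <= 0) stop("pulse_width_us must be > 0")
  if (frequency_hz <= 0) stop("frequency_hz must be > 0")
  amplitude_unit <- match.arg(amplitude_unit, c("V", "mA"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  df <- data.frame(patient_id = as.character(patient_id),
                   contact_x = contact_mm[1], contact_y = contact_mm[2],
                   contact_z = contact_mm[3],
                   amplitude = amplitude, amplitude_unit = amplitude_unit,
                   pulse_width_us = pulse_width_us,
                   frequency_hz = frequency_hz, hemisphere = hemisphere,
                   stringsAsFactors = FALSE)
  class(df) <- c("electrode_stims", "data.frame")
  df
}

#' Combine electrode stimulation records
#'
#' @param ... `electrode_stims` rows or compatible data.frames.
#' @return `electrode_stims` data.frame.
#' @export
bind_stims <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("electrode_stims", "data.frame")
  df
}

#' Read electrode stimulation records from JSON
#'
#' The JSON is an array of objects with fields `patient_id`,
#' `contact_mm` (length-3 array), `amplitude`, `amplitude_unit`,
#' `pulse_width_us`, `frequency_hz`, `hemisphere`.
#'
#' @param path JSON file.
#' @return `electrode_stims` data.frame.
#' @export
read_stims <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(x, function(s)
    electrode_stim(s$patient_id, unlist(s$contact_mm), s$amplitude,
                   s$amplitude_unit %||% "V", s$pulse_width_us %||% 60,
                   s$frequency_hz %||% 130, s$hemisphere %||% "right"))
  do.call(bind_stims, rows)
}

#' Write electrode stimulation records to JSON
#'
#' @param stims `electrode_stims` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stims <- function(stims, path) {
  recs <- lapply(seq_len(nrow(stims)), function(i)
    list(patient_id = stims$patient_id[i],
         contact_mm = c(stims$contact_x[i], stims$contact_y[i],
                        stims$contact_z[i]),
         amplitude = stims$amplitude[i],
         amplitude_unit = stims$amplitude_unit[i],
         pulse_width_us = stims$pulse_width_us[i],
         frequency_hz = stims$frequency_hz[i],
         hemisphere = stims$hemisphere[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
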