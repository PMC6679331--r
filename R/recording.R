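#' Multi-channel EGG recording
#'
#' An `egg_recording` bundles three cutaneous EGG channels and one force
#' sensing resistor (FSR) pushbutton channel, uniformly sampled at a common
#' rate, together with acquisition metadata. EGG channels are stored
#' input-referred in microvolts; the FSR channel is in arbitrary
#' non-negative units and is used only for session synchronisation.
#'
#' @param channels A list of three equal-length numeric vectors (µV), or a
#'   numeric matrix with three columns.
#' @param fsr Numeric vector of FSR samples, same length as the channels;
#'   all values must be non-negative.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param subject_id Subject identifier (single string).
#' @param start_time Optional acquisition start time (`POSIXct` or `NULL`).
#' @param gain Amplifier gain applied during acquisition (recorded as
#'   metadata; the stored samples are already referred to the input).
#' @param notes Free-text notes.
#'
#' @return An object of class `egg_recording`: a list with elements
#'   `data` (a tibble with columns `time_s`, `ch1_uV`, `ch2_uV`, `ch3_uV`,
#'   `fsr`), `fs`, `subject_id`, `start_time`, `gain` and `notes`.
#' @export
#' @examples
#' t <- seq(0, 59.5, by = 0.5)
#' ch <- replicate(3, 150 * sin(2 * pi * 0.05 * t), simplify = FALSE)
#' rec <- egg_recording(ch, fsr = rep(0, length(t)), fs = 2, subject_id = "S1")
#' rec
egg_recording <- function(channels, fsr, fs, subject_id,
                          start_time = NULL, gain = NA_real_, notes = "") {
  if (is.matrix(channels)) {
    stopifnot(ncol(channels) == 3)
    channels <- list(channels[, 1], channels[, 2], channels[, 3])
  }
  if (!is.list(channels) || length(channels) != 3) {
    stop("`channels` must be a list of three numeric vectors", call. = FALSE)
  }
  n <- unique(lengths(channels))
  if (length(n) != 1 || n < 2) {
    stop("channels must have equal length >= 2", call. = FALSE)
  }
  if (length(fsr) != n) {
    stop("`fsr` must have the same length as the channels", call. = FALSE)
  }
  if (any(fsr < 0)) stop("FSR samples must be non-negative", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a positive scalar", call. = FALSE)
  }
  data <- tibble::tibble(
    time_s = seq(0, by = 1 / fs, length.out = n),
    ch1_uV = as.numeric(channels[[1]]),
    ch2_uV = as.numeric(channels[[2]]),
    ch3_uV = as.numeric(channels[[3]]),
    fsr    = as.numeric(fsr)
  )
  structure(
    list(data = data, fs = fs, subject_id = as.character(subject_id),
         start_time = start_time, gain = gain, notes = notes),
    class = "egg_recording"
  )
}

#' @export
print.egg_recording <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf(
    "<egg_recording> subject %s: 3 EGG channels + FSR, %d samples at %g Hz (%.1f s)\n",
    x$subject_id, n, x$fs, n / x$fs
  ))
  print(x$data, n = 5)
  invisible(x)
}

#' Extract the EGG channels of a recording as a list
#'
#' @param rec An [egg_recording()].
#' @return A list of three numeric vectors (µV).
#' @export
recording_channels <- function(rec) {
  stopifnot(inherits(rec, "egg_recording"))
  list(rec$data$ch1_uV, rec$data$ch2_uV, rec$data$ch3_uV)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read an EGG recording from a CSV file with a JSON sidecar
#'
#' The CSV must contain the header columns `time_s`, `ch1_uV`, `ch2_uV`,
#' `ch3_uV` and `fsr` (in any order); the sidecar (same path with a
#' `.json` extension) carries `fs_hz` and `subject_id`, optionally
#' `gain` and `notes`. The time column is checked for uniform spacing
#' consistent with the declared sampling rate to within 1 µs.
#'
#' @param path Path to the recording CSV.
#' @return An [egg_recording()].
#' @export
read_recording <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "ch1_uV", "ch2_uV", "ch3_uV", "fsr")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("recording format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("metadata error: sidecar not found: ", side, call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs_hz) || is.null(meta$subject_id)) {
    stop("metadata error: sidecar must contain fs_hz and subject_id",
         call. = FALSE)
  }
  fs <- as.numeric(meta$fs_hz)
  dt <- diff(df$time_s)
  if (length(dt) == 0) stop("recording must have length >= 2", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-6) {
    stop("sampling error: time column is not uniformly spaced", call. = FALSE)
  }
  if (abs(dt[1] - 1 / fs) > 1e-6) {
    stop(sprintf(
      "metadata error: time step %.6g s inconsistent with sidecar fs = %g Hz",
      dt[1], fs), call. = FALSE)
  }
  egg_recording(
    channels = list(df$ch1_uV, df$ch2_uV, df$ch3_uV),
    fsr = df$fsr, fs = fs, subject_id = meta$subject_id,
    gain = if (is.null(meta$gain)) NA_real_ else as.numeric(meta$gain),
    notes = if (is.null(meta$notes)) "" else meta$notes
  )
}

#' Write an EGG recording to CSV plus JSON sidecar
#'
#' Values are printed with enough digits (15 significant) that
#' [read_recording()] inverts the write exactly at double precision.
#'
#' @param rec An [egg_recording()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return The CSV path, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "egg_recording"))
  readr::write_csv(rec$data, path, progress = FALSE)
  meta <- list(fs_hz = rec$fs, subject_id = rec$subject_id,
               gain = rec$gain, notes = rec$notes)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
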