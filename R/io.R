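# File interfaces: PCG as IEEE-float WAV, ECG/motion as CSV (t_ms, value),
# annotations and reports as JSON. All times ms, indices 0-based, windows
# half-open.

#' Write a mono trace as an IEEE float32 WAV file
#'
#' @param x Numeric trace.
#' @param fs_hz Sampling rate, Hz.
#' @param path Output path.
#' @export
write_wav <- function(x, fs_hz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs_hz), con, size = 4, endian = "little")
  writeBin(as.integer(fs_hz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono IEEE float32 or PCM16 WAV file
#'
#' @param path WAV path.
#' @return List with `x` (numeric trace) and `fs_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  stop_if(riff != "RIFF", sprintf("'%s' is not a RIFF/WAV file", path))
  readBin(con, "integer", 1, size = 4, endian = "little")
  stop_if(readChar(con, 4) != "WAVE", sprintf("'%s' is not a WAV file", path))
  fmt <- NULL
  repeat {
    raw_id <- readBin(con, "raw", 4)
    stop_if(length(raw_id) < 4, sprintf("'%s': no data chunk found", path))
    id <- rawToChar(raw_id)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      code <- readBin(con, "integer", 1, size = 2, endian = "little")
      nch <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      stop_if(nch != 1, sprintf("'%s': only mono WAV supported", path))
      fmt <- list(code = code, fs = fs, bits = bits)
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      stop_if(is.null(fmt), sprintf("'%s': data chunk before fmt", path))
      if (fmt$code == 3 && fmt$bits == 32) {
        x <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      } else if (fmt$code == 1 && fmt$bits == 16) {
        x <- readBin(con, "integer", sz / 2, size = 2,
                     endian = "little") / 32768
      } else {
        stop(sprintf("'%s': unsupported WAV format (code %d, %d bit)",
                     path, fmt$code, fmt$bits), call. = FALSE)
      }
      return(list(x = x, fs_hz = fmt$fs))
    } else {
      readBin(con, "raw", sz)
    }
  }
}

#' Write a recording to disk
#'
#' PCG as float WAV, ECG (and motion, when present) as CSV with columns
#' `t_ms, value`, metadata as JSON.
#'
#' @param rec An `acg_recording`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Named list of the written paths.
#' @export
write_recording <- function(rec, dir, stem = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_ms <- idx_to_ms(seq_along(rec$ecg), rec$fs_hz)
  paths <- list(
    pcg = file.path(dir, paste0(stem, "_pcg.wav")),
    ecg = file.path(dir, paste0(stem, "_ecg.csv")),
    meta = file.path(dir, paste0(stem, "_meta.json"))
  )
  write_wav(rec$pcg, rec$fs_hz, paths$pcg)
  utils::write.csv(data.frame(t_ms = t_ms, ecg_mv = rec$ecg),
                   paths$ecg, row.names = FALSE)
  if (!is.null(rec$motion)) {
    paths$motion <- file.path(dir, paste0(stem, "_motion.csv"))
    utils::write.csv(data.frame(t_ms = t_ms, accel_g = rec$motion),
                     paths$motion, row.names = FALSE)
  }
  jsonlite::write_json(list(fs_hz = rec$fs_hz, duration_ms = rec$duration_ms,
                            n_samples = length(rec$ecg)),
                       paths$meta, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a recording from disk
#'
#' Rebuilds an `acg_recording` from the files written by
#' [write_recording()]. Traces must agree in length; the WAV sampling rate
#' must match the expected rate unless `resample = TRUE`, in which case the
#' PCG is linearly resampled.
#'
#' @param pcg_path WAV path for the PCG.
#' @param ecg_path CSV path for the ECG (`t_ms, ecg_mv`).
#' @param motion_path Optional CSV path for the motion channel
#'   (`t_ms, accel_g`).
#' @param fs_hz Expected sampling rate; `NULL` accepts the WAV's rate.
#' @param resample Resample the PCG on rate mismatch instead of erroring.
#' @return An `acg_recording`.
#' @export
read_recording <- function(pcg_path, ecg_path, motion_path = NULL,
                           fs_hz = NULL, resample = FALSE) {
  wav <- read_wav(pcg_path)
  ecg_df <- utils::read.csv(ecg_path)
  stop_if(!all(c("t_ms", "ecg_mv") %in% names(ecg_df)),
          sprintf("'%s': expected columns t_ms, ecg_mv", ecg_path))
  pcg <- wav$x
  rate <- wav$fs_hz
  if (!is.null(fs_hz) && fs_hz != rate) {
    stop_if(!resample,
            sprintf("'%s': WAV rate %d Hz != expected %d Hz", pcg_path,
                    rate, fs_hz))
    n_new <- round(length(pcg) * fs_hz / rate)
    pcg <- resample_to(pcg, n_new)
    rate <- fs_hz
  }
  stop_if(length(pcg) != nrow(ecg_df),
          sprintf("trace length mismatch: %s has %d samples, %s has %d rows",
                  pcg_path, length(pcg), ecg_path, nrow(ecg_df)))
  motion <- NULL
  if (!is.null(motion_path)) {
    mo <- utils::read.csv(motion_path)
    stop_if(!all(c("t_ms", "accel_g") %in% names(mo)),
            sprintf("'%s': expected columns t_ms, accel_g", motion_path))
    stop_if(nrow(mo) != length(pcg),
            sprintf("'%s': motion length mismatch", motion_path))
    motion <- mo$accel_g
  }
  new_recording(ecg_df$ecg_mv, pcg, motion, rate)
}

#' Write an analysis report as JSON
#'
#' Serializes any result list (quality reports, per-recording parameters,
#' diagnostic-model reports) to pretty-printed JSON, with the configuration
#' embedded for provenance when supplied.
#'
#' @param results List of results.
#' @param path Output path.
#' @param config Optional `acg_config` to embed.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, config = NULL) {
  if (!is.null(config)) results$config <- unclass(config)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(strip_classes(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

# drop S3 classes / model fits that do not serialize cleanly
strip_classes <- function(x) {
  if (inherits(x, "glm")) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    x <- lapply(unclass(x), strip_classes)
    return(x[!vapply(x, is.null, logical(1))])
  }
  x
}

#' Write a cohort table as CSV
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV path; must contain `group` plus at least one predictor
#'   column.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  stop_if(!"group" %in% names(df),
          sprintf("'%s': cohort CSV needs a 'group' column", path))
  df
}
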