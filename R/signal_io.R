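# Recording containers: WAV (RIFF PCM-16 / IEEE float-32) for signals, CSV
# for signals and metadata. The RIFF reader/writer is minimal but chunk-walking,
# so files from standard tools (scipy.io.wavfile, sox) load fine.

.wav_read_header <- function(con) {
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("unreadable header: not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("unreadable header: not a WAVE file")
}

#' Read a two-channel cuff recording
#'
#' Reads a recording from a WAV container (channel 0 = sound, channel 1 =
#' cuff pressure when stereo) or from a CSV file with columns
#' `time`/`index`, `sound`, `pressure` and a `# fs=<Hz>` header line.
#' WAV amplitudes are preserved up to the container's linear quantization:
#' float-32 files round-trip to ~1e-7 relative, PCM-16 files are stored
#' peak-normalized (see [write_recording()]) so absolute units are lost but
#' waveform shape is preserved.
#'
#' @param path file path.
#' @param format `"wav"` or `"csv"`; default guesses from the extension.
#' @param subject_id identifier attached to the returned recording.
#' @return A [koro_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "wav", "csv"),
                           subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wav"
  if (!file.exists(path)) stop("missing file: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "wav") .read_wav(path, subject_id) else .read_csv_rec(path, subject_id)
}

.read_wav <- function(path, subject_id) {
  con <- file(path, "rb"); on.exit(close(con))
  .wav_read_header(con)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      body <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(body[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("unreadable header: missing fmt/data chunk")
  x <- switch(as.character(fmt$audio_format),
    "1" = readBin(data_raw, "integer", length(data_raw) / 2L, 2,
                  signed = TRUE, endian = "little") / 32768,
    "3" = readBin(data_raw, "double", length(data_raw) / 4L, 4,
                  endian = "little"),
    stop("unreadable header: unsupported WAV audio format ", fmt$audio_format))
  if (!all(is.finite(x))) stop("non-finite samples in ", path)
  nc <- fmt$n_channels
  if (!nc %in% c(1L, 2L)) stop("expected mono or stereo WAV, got ", nc, " channels")
  if (nc == 2L) {
    koro_recording(sound = x[seq(1, length(x), by = 2)],
                   cuff_pressure = x[seq(2, length(x), by = 2)],
                   fs = fmt$sample_rate, subject_id = subject_id)
  } else {
    koro_recording(sound = x, fs = fmt$sample_rate, subject_id = subject_id)
  }
}

.read_csv_rec <- function(path, subject_id) {
  hdr <- readLines(path, n = 5L)
  fs_line <- grep("^#\\s*fs\\s*=", hdr, value = TRUE)
  if (!length(fs_line)) stop("unreadable header: csv lacks '# fs=<Hz>' line")
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[1]))
  df <- read.csv(path, comment.char = "#")
  if (!"sound" %in% names(df)) stop("unreadable header: csv lacks 'sound' column")
  press <- if ("pressure" %in% names(df)) df$pressure else NULL
  if (!is.null(press)) {
    n_ok <- sum(!is.na(df$sound)); p_ok <- sum(!is.na(press))
    if (n_ok != p_ok)
      stop("channel-length mismatch: sound has ", n_ok,
           " samples, pressure has ", p_ok)
  }
  koro_recording(sound = df$sound[!is.na(df$sound)],
                 cuff_pressure = if (is.null(press)) NULL else press[!is.na(press)],
                 fs = fs, subject_id = subject_id)
}

#' Write a recording to disk
#'
#' WAV export defaults to IEEE float-32, which round-trips both channels
#' (including the mmHg pressure channel) essentially exactly. PCM-16 export
#' peak-normalizes the file to 0.99 full scale across both channels before
#' quantizing, a documented linear scaling that avoids clipping while
#' keeping quantization error below `1/32768` of the peak.
#'
#' @param rec a [koro_recording()].
#' @param path destination file.
#' @param format `"wav"` or `"csv"`; guessed from the extension by default.
#' @param bits for WAV, 32 (float) or 16 (PCM).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "wav", "csv"),
                            bits = 32) {
  stopifnot(inherits(rec, "koro_recording"))
  if (length(rec$sound) < 1L) stop("zero-length sound channel")
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wav"
  if (format == "wav") .write_wav(rec, path, bits) else .write_csv_rec(rec, path)
  invisible(path)
}

.write_wav <- function(rec, path, bits) {
  stopifnot(bits %in% c(16, 32))
  nch <- if (is.null(rec$cuff_pressure)) 1L else 2L
  x <- if (nch == 2L) as.vector(rbind(rec$sound, rec$cuff_pressure)) else rec$sound
  con <- file(path, "wb")
  if (!isOpen(con)) stop("unwritable path: ", path)
  on.exit(close(con))
  bytes_per <- bits / 8L
  data_size <- length(x) * bytes_per
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(if (bits == 16) 1L else 3L); w16(nch)
  w32(as.integer(round(rec$fs)))
  w32(as.integer(round(rec$fs)) * nch * bytes_per)
  w16(nch * bytes_per); w16(as.integer(bits))
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bits == 16) {
    peak <- max(abs(x), 1e-12)
    q <- as.integer(pmin(pmax(round(x / peak * 0.99 * 32768), -32768), 32767))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.double(x), con, 4, endian = "little")
  }
}

.write_csv_rec <- function(rec, path) {
  con <- file(path, "w")
  if (!isOpen(con)) stop("unwritable path: ", path)
  writeLines(sprintf("# fs=%g", rec$fs), con)
  close(con)
  df <- data.frame(time = (seq_along(rec$sound) - 1) / rec$fs,
                   sound = rec$sound)
  if (!is.null(rec$cuff_pressure)) df$pressure <- rec$cuff_pressure
  suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                               col.names = TRUE, append = TRUE, quote = FALSE))
}

#' Load a cohort metadata table
#'
#' Reads a CSV whose header names the [koro_subject()] fields
#' (`subject_id, age, sex, bmi, sbp, dbp, heart_rate, diabetes, smoking,
#' group_label, bapwv`; `bapwv`, `smoking`, `group_label` optional).
#' Booleans are parsed from `0/1/yes/no/true/false`. Row-level invariant
#' violations (e.g. `sbp <= dbp`) raise an error naming the row.
#'
#' @param path CSV file path.
#' @return list of [koro_subject()] records.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("subject_id", "age", "sex", "bmi", "sbp", "dbp",
                 "heart_rate", "diabetes")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("age", "bmi", "sbp", "dbp", "heart_rate")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) stop("non-numeric value in column '", col, "'")
    df[[col]] <- v
  }
  parse_bool <- function(v) {
    v <- tolower(trimws(as.character(v)))
    out <- v %in% c("1", "yes", "true", "y")
    bad <- !v %in% c("1", "yes", "true", "y", "0", "no", "false", "n")
    if (any(bad)) stop("unparseable boolean value: ", v[bad][1])
    out
  }
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tryCatch(
      koro_subject(
        subject_id = r$subject_id, age = r$age, sex = tolower(r$sex),
        bmi = r$bmi, sbp = r$sbp, dbp = r$dbp, heart_rate = r$heart_rate,
        diabetes = parse_bool(r$diabetes),
        smoking = if ("smoking" %in% names(df)) parse_bool(r$smoking) else FALSE,
        group_label = if ("group_label" %in% names(df)) r$group_label else "none",
        bapwv = if ("bapwv" %in% names(df) && !is.na(r$bapwv) &&
                    nzchar(as.character(r$bapwv)))
          as.numeric(r$bapwv) else NA_real_),
      error = function(e) stop("row ", i, " (", r$subject_id, "): ",
                               conditionMessage(e), call. = FALSE))
  })
}

#' Write a cohort metadata table
#' @param subjects list of [koro_subject()] records.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(subjects, path) {
  write.csv(cohort_to_df(subjects), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
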