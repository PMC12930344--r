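#' Construct a two-channel cuff recording
#'
#' A `koro_recording` bundles the microphone signal and the cuff-pressure
#' channel of one cuff-deflation measurement. Both channels are stored at
#' the same sampling rate `fs`; a pressure channel acquired at a different
#' rate should be resampled on ingest (see [read_recording()]). Sound
#' amplitudes are in arbitrary sensor units; every scale-sensitive feature
#' downstream documents this. Sample indices are 0-based and windows are
#' half-open `[start, end)`.
#'
#' @param sound numeric vector, microphone samples (arbitrary units).
#' @param cuff_pressure numeric vector of the same length, cuff pressure in
#'   mmHg. May be `NULL` when only the acoustic channel exists.
#' @param fs sampling rate in Hz (the reference device samples at 1000 Hz).
#' @param subject_id opaque subject identifier.
#' @param annotations optional list with 0-based half-open integer fields
#'   `start`, `end` marking a known Korotkoff window.
#' @return An object of class `koro_recording`.
#' @examples
#' rec <- koro_recording(sin(2 * pi * 32 * seq(0, 1, by = 1e-3)), fs = 1000)
#' rec$fs
#' @export
koro_recording <- function(sound, cuff_pressure = NULL, fs = 1000,
                           subject_id = "anon", annotations = NULL) {
  sound <- as.numeric(sound)
  if (length(sound) < 1L) stop("sound must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  fs <- as.numeric(fs)
  if (!all(is.finite(sound))) stop("non-finite samples in sound channel")
  if (!is.null(cuff_pressure)) {
    cuff_pressure <- as.numeric(cuff_pressure)
    if (length(cuff_pressure) != length(sound))
      stop("channel-length mismatch: sound has ", length(sound),
           " samples, cuff_pressure has ", length(cuff_pressure))
    if (!all(is.finite(cuff_pressure)))
      stop("non-finite samples in cuff_pressure channel")
  }
  if (!is.null(annotations)) {
    s <- annotations$start; e <- annotations$end
    if (is.null(s) || is.null(e) || s < 0 || s >= e || e > length(sound))
      stop("annotations must satisfy 0 <= start < end <= length(sound)")
    annotations <- list(start = as.integer(s), end = as.integer(e))
  }
  structure(
    list(sound = sound, cuff_pressure = cuff_pressure, fs = fs,
         subject_id = as.character(subject_id), annotations = annotations),
    class = "koro_recording")
}

#' @export
print.koro_recording <- function(x, ...) {
  cat(sprintf("<koro_recording> subject=%s  %d samples @ %g Hz (%.2f s)%s%s\n",
              x$subject_id, length(x$sound), x$fs, length(x$sound) / x$fs,
              if (is.null(x$cuff_pressure)) "" else "  + pressure channel",
              if (is.null(x$annotations)) "" else
                sprintf("  [window %d,%d)", x$annotations$start,
                        x$annotations$end)))
  invisible(x)
}

#' @export
length.koro_recording <- function(x) length(x$sound)

#' Construct a subject metadata record
#'
#' Holds the per-subject covariates used by the statistical pipeline: age,
#' sex, BMI, brachial blood pressures, heart rate, diabetes and smoking
#' status, an analysis group label, and (for hospital cohorts) the measured
#' brachial-ankle pulse wave velocity in cm/s.
#'
#' @param subject_id identifier linking the subject to recordings.
#' @param age years, positive.
#' @param sex `"male"` or `"female"`.
#' @param bmi body-mass index, kg/m^2.
#' @param sbp,dbp systolic/diastolic pressure in mmHg; `sbp > dbp > 0`.
#' @param heart_rate beats per minute, positive.
#' @param diabetes,smoking logical.
#' @param group_label one of `"older"`, `"young"`, `"high_baPWV"`,
#'   `"low_baPWV"`, `"none"`.
#' @param bapwv brachial-ankle pulse wave velocity (cm/s) or `NA`.
#' @return An object of class `koro_subject` (a named list).
#' @export
koro_subject <- function(subject_id, age, sex = c("male", "female"),
                         bmi, sbp, dbp, heart_rate,
                         diabetes = FALSE, smoking = FALSE,
                         group_label = "none", bapwv = NA_real_) {
  sex <- match.arg(sex)
  group_label <- match.arg(group_label,
                           c("none", "young", "older", "high_baPWV", "low_baPWV"))
  if (!is.finite(age) || age <= 0) stop("age must be > 0")
  if (!is.finite(sbp) || !is.finite(dbp) || !(sbp > dbp) || dbp <= 0)
    stop("blood pressures must satisfy sbp > dbp > 0")
  if (!is.finite(heart_rate) || heart_rate <= 0) stop("heart_rate must be > 0")
  if (!is.na(bapwv) && bapwv <= 0) stop("bapwv, when present, must be > 0")
  structure(list(subject_id = as.character(subject_id), age = age, sex = sex,
                 bmi = bmi, sbp = sbp, dbp = dbp, heart_rate = heart_rate,
                 diabetes = isTRUE(diabetes), smoking = isTRUE(smoking),
                 group_label = group_label, bapwv = bapwv),
            class = "koro_subject")
}

#' Convert a list of subjects to a data frame
#'
#' @param subjects list of [koro_subject()] records.
#' @return data.frame with one row per subject.
#' @export
cohort_to_df <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               bmi = s$bmi, sbp = s$sbp, dbp = s$dbp,
               heart_rate = s$heart_rate,
               diabetes = as.integer(s$diabetes),
               smoking = as.integer(s$smoking),
               group_label = s$group_label, bapwv = s$bapwv,
               stringsAsFactors = FALSE)))
}
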