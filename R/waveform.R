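#' Uniformly sampled physiological waveform
#'
#' Container for one channel of a recording: a finger PPG (arbitrary units)
#' or an invasive arterial blood pressure signal (mmHg).
#'
#' @param samples numeric vector, finite values.
#' @param fs sampling rate in Hz, > 0.
#' @param subject_id subject identifier.
#' @param channel "ppg" or "abp".
#' @param t0 time of the first sample in seconds.
#' @return object of class `waveform_recording`.
#' @export
waveform_recording <- function(samples, fs, subject_id = "s1",
                               channel = c("ppg", "abp"), t0 = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(samples) < 1L) stop("samples must have length >= 1")
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = samples, fs = fs, subject_id = subject_id,
                 channel = channel, t0 = t0),
            class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("<waveform_recording> subject %s, channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

duration_s <- function(sig) length(sig$samples) / sig$fs

#' Read a waveform from a two-column CSV/TSV file
#'
#' Expects columns `time_s` and `value`; the sampling rate is inferred from
#' the median time step (must be uniform to 1e-6 s).
#'
#' @param path file path; separator inferred from extension (.tsv -> tab).
#' @param subject_id,channel metadata attached to the recording.
#' @return a [waveform_recording()].
#' @export
read_waveform_csv <- function(path, subject_id = "s1", channel = "ppg") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("waveform file must have columns time_s,value")
  dt <- diff(d$time_s)
  if (max(abs(dt - median(dt))) > 1e-6) stop("non-uniform sampling in ", path)
  waveform_recording(d$value, fs = 1 / median(dt), subject_id = subject_id,
                     channel = channel, t0 = d$time_s[1])
}

#' Write a waveform to CSV
#' @param sig a [waveform_recording()].
#' @param path output path.
#' @export
write_waveform_csv <- function(sig, path) {
  t <- sig$t0 + (seq_along(sig$samples) - 1) / sig$fs
  utils::write.csv(data.frame(time_s = t, value = sig$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a demographics table
#'
#' Header must contain subject_id, age, weight, height, gender. Gender is
#' accepted as 0/1 or m/f (male -> 1).
#'
#' @param path CSV path.
#' @return data.frame with numeric age/weight/height and 0/1 gender.
#' @export
read_demographics <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "weight", "height", "gender")
  if (!all(need %in% names(d))) stop("demographics must have columns ", paste(need, collapse = ","))
  if (is.character(d$gender))
    d$gender <- as.integer(tolower(substr(d$gender, 1, 1)) == "m")
  d
}
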