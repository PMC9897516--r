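# Pulse wave analysis: PPG derivatives, fiducial points of the velocity /
# acceleration / jerk plethysmograms, and morphological features.

#' Derivatives of an ensemble-average pulse
#'
#' Central-difference differentiation (one-sided at the endpoints) followed
#' by light Savitzky-Golay smoothing between orders gives the velocity (VPG),
#' acceleration (APG) and jerk (JPG) plethysmograms, time-aligned with the
#' pulse.
#'
#' @param pulse an `ensemble_pulse`, or a numeric vector with `fs_pulse`.
#' @param fs_pulse sampling rate of the pulse (Hz); taken from the pulse
#'   object if omitted.
#' @param sg_window Savitzky-Golay window length (odd, samples); by default
#'   a 25 ms window (at least 7 samples), so smoothing is fixed in time
#'   rather than in samples.
#' @return list of class `derivative_set`: ppg, vpg, apg, jpg, fs_pulse.
#' @export
pulse_derivatives <- function(pulse, fs_pulse = NULL, sg_window = NULL) {
  x <- if (inherits(pulse, "ensemble_pulse")) pulse$waveform else as.numeric(pulse)
  fs <- fs_pulse %||% pulse$fs_pulse
  if (length(x) < 16) stop("pulse_derivatives: pulse too short (< 16 samples)")
  if (is.null(sg_window)) {
    sg_window <- max(7L, round(0.025 * fs))
    if (sg_window %% 2L == 0L) sg_window <- sg_window + 1L
  }
  sg_window <- min(sg_window, length(x) - (1 - length(x) %% 2))
  deriv <- function(v) {
    n <- length(v)
    d <- numeric(n)
    d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    d[1] <- v[2] - v[1]
    d[n] <- v[n] - v[n - 1]
    signal::sgolayfilt(d * fs, p = 3, n = sg_window, m = 0)
  }
  vpg <- deriv(x)
  apg <- deriv(vpg)
  jpg <- deriv(apg)
  structure(list(ppg = x, vpg = vpg, apg = apg, jpg = jpg, fs_pulse = fs),
            class = "derivative_set")
}

#' Fiducial points of a pulse and its derivatives
#'
#' Detected on a single onset-aligned pulse (first sample = foot):
#' \itemize{
#'   \item PPG: `sys_peak` (global maximum), `dicrotic_notch` (at the VPG
#'     z-wave time, the velocity rebound between the systolic and reflected
#'     waves), `dia_peak` (first PPG local maximum after the notch;
#'     fallback: negative-slope inflection, i.e. a local maximum of the VPG
#'     below zero marking a reflected-wave shoulder).
#'   \item VPG: `w` (global maximum), `y` (first local minimum after the
#'     systolic peak), `z` (next local maximum after y).
#'   \item APG: `a`-`e`, the first five alternating local extrema starting
#'     from the first local maximum (a max, b min, c max, d min, e max).
#'   \item JPG: `p0`-`p3`, the first four alternating local extrema.
#' }
#' Each point carries its time from the pulse foot (s) and its amplitude on
#' its own signal. Missing (degenerate) points are absent from the result.
#'
#' @param d a `derivative_set` from [pulse_derivatives()].
#' @param fs_pulse sampling rate (Hz); taken from `d` if omitted.
#' @param min_prom minimum extremum prominence as a fraction of each
#'   signal's range; adjacent ripple pairs below it are discarded.
#' @return named list of class `fiducial_set`; each element is
#'   `c(t = seconds, a = amplitude)`.
#' @export
detect_fiducials <- function(d, fs_pulse = NULL, min_prom = 0.02) {
  fs <- fs_pulse %||% d$fs_pulse
  out <- list()
  pt <- function(sig, idx) c(t = (unname(idx) - 1) / fs, a = unname(sig[idx]))
  extrema <- function(sig) {
    rng <- diff(range(sig))
    prune_extrema(local_extrema(sig), sig, min_prom * rng)
  }

  # systolic peak: first dominant local maximum (the systolic wave precedes
  # the reflected wave, which can rival it in amplitude); fallback global max
  ex_p0 <- extrema(d$ppg)
  pk <- ex_p0$idx[ex_p0$type == "max" & d$ppg[ex_p0$idx] >=
                    min(d$ppg) + 0.75 * diff(range(d$ppg))]
  sys_idx <- if (length(pk)) pk[1] else which.max(d$ppg)
  out$ppg.sys_peak <- pt(d$ppg, sys_idx)

  ex_v <- extrema(d$vpg)
  w_idx <- which.max(d$vpg)
  out$vpg.w <- pt(d$vpg, w_idx)
  y_idx <- ex_v$idx[ex_v$type == "min" & ex_v$idx > sys_idx][1]
  if (!is.na(y_idx)) {
    out$vpg.y <- pt(d$vpg, y_idx)
    z_idx <- ex_v$idx[ex_v$type == "max" & ex_v$idx > y_idx][1]
    if (!is.na(z_idx)) out$vpg.z <- pt(d$vpg, z_idx)
  }

  ex_a <- extrema(d$apg)
  a_pos <- which(ex_a$type == "max")[1]
  if (!is.na(a_pos)) {
    seq_idx <- ex_a$idx[a_pos:nrow(ex_a)]  # extrema alternate by construction
    nm <- c("apg.a", "apg.b", "apg.c", "apg.d", "apg.e")
    for (k in seq_len(min(5L, length(seq_idx))))
      out[[nm[k]]] <- pt(d$apg, seq_idx[k])
  }

  ex_j <- extrema(d$jpg)
  if (nrow(ex_j) > 0) {
    nm <- paste0("jpg.p", 0:3)
    for (k in seq_len(min(4L, nrow(ex_j))))
      out[[nm[k]]] <- pt(d$jpg, ex_j$idx[k])
  }

  # dicrotic notch at the VPG z-wave (the velocity rebound between the
  # systolic and reflected waves); absent when there is no reflected wave
  notch_idx <- NA_integer_
  if (!is.null(out$vpg.z)) notch_idx <- as.integer(round(out$vpg.z[["t"]] * fs)) + 1L
  if (!is.na(notch_idx) && notch_idx <= length(d$ppg) && notch_idx > sys_idx) {
    out$ppg.dicrotic_notch <- pt(d$ppg, notch_idx)
    ex_p <- extrema(d$ppg)
    dia_idx <- ex_p$idx[ex_p$type == "max" & ex_p$idx > notch_idx][1]
    if (is.na(dia_idx)) {
      # inflection fallback: reflected-wave shoulder = local max of VPG at
      # or after the notch while the pulse is still falling (vpg < 0)
      cand <- ex_v$idx[ex_v$type == "max" & ex_v$idx >= notch_idx]
      cand <- cand[d$vpg[cand] < 0]
      if (length(cand)) dia_idx <- cand[1]
    }
    if (!is.na(dia_idx)) out$ppg.dia_peak <- pt(d$ppg, dia_idx)
  }
  structure(out, class = "fiducial_set", fs_pulse = fs)
}

#' Morphological features of an ensemble-average pulse
#'
#' With notch time Tn and pulse duration T (signal units are those of the
#' PPG): MAP = mean over [0, T]; MSBP / MDBP = means over [0, Tn] / [Tn, T];
#' ESP = pulse value at Tn; SPTI / DPTI = trapezoidal integrals over the same
#' intervals; SEVR = DPTI / SPTI; PI = 100 * (pulsatile amplitude, half the
#' pulse max - min swing) / DC, with DC the unfiltered window mean;
#' AIx = 100 * (systolic peak - inflection) /
#' pulse amplitude with the inflection read at the APG d-wave time
#' (configurable), and AIx75 = AIx + k (HR - 75) with k = 0.48 %/bpm. The
#' times and amplitudes of every fiducial point are appended.
#'
#' @param pulse an `ensemble_pulse`.
#' @param d its `derivative_set`.
#' @param f its `fiducial_set`.
#' @param dc DC offset for the perfusion index (unfiltered window mean).
#' @param aix_point fiducial whose time defines the AIx inflection.
#' @param aix_hr_slope heart-rate correction slope k in %/bpm.
#' @return named numeric vector (NA where a required fiducial is missing).
#' @export
pulse_features <- function(pulse, d, f, dc = NA_real_,
                           aix_point = "apg.d", aix_hr_slope = 0.48) {
  x <- pulse$waveform
  fs <- pulse$fs_pulse
  L <- length(x)
  t <- (seq_len(L) - 1) / fs
  fv <- c(MAP = mean(x))
  notch <- f$ppg.dicrotic_notch
  if (!is.null(notch)) {
    ni <- as.integer(round(notch[["t"]] * fs)) + 1L
    fv["MSBP"] <- mean(x[1:ni])
    fv["MDBP"] <- mean(x[ni:L])
    fv["ESP"] <- x[ni]
    fv["SPTI"] <- trapz(t[1:ni], x[1:ni])
    fv["DPTI"] <- trapz(t[ni:L], x[ni:L])
    fv["SEVR"] <- fv[["DPTI"]] / fv[["SPTI"]]
  } else {
    fv[c("MSBP", "MDBP", "ESP", "SPTI", "DPTI", "SEVR")] <- NA_real_
  }
  amp <- max(x) - min(x)
  # AC term is the pulsatile amplitude (half the peak-to-trough swing)
  fv["PI"] <- if (is.finite(dc) && dc > 0) 100 * (amp / 2) / dc else NA_real_
  infl <- f[[aix_point]]
  if (!is.null(infl) && amp > 0) {
    ii <- as.integer(round(infl[["t"]] * fs)) + 1L
    aix <- 100 * (max(x) - x[min(ii, L)]) / amp
    fv["AIx75"] <- aix + aix_hr_slope * (pulse$hr - 75)
  } else fv["AIx75"] <- NA_real_
  fv["HR"] <- pulse$hr
  for (nm in names(f)) {
    fv[paste0(nm, ".t")] <- f[[nm]][["t"]]
    fv[paste0(nm, ".a")] <- f[[nm]][["a"]]
  }
  fv
}

# Canonical fiducial names: missing points become NA columns so every window
# yields the same feature set.
fiducial_names <- function() {
  pts <- c("ppg.sys_peak", "ppg.dicrotic_notch", "ppg.dia_peak",
           "vpg.w", "vpg.y", "vpg.z",
           paste0("apg.", letters[1:5]), paste0("jpg.p", 0:3))
  as.vector(t(outer(pts, c(".t", ".a"), paste0)))
}

#' Append demographics to a feature vector
#'
#' @param fv named numeric feature vector.
#' @param demo list or 1-row data.frame with age (y), weight (kg),
#'   height (cm) and gender (0/1 or "m"/"f"); all four required.
#' @return fv with exactly four entries appended.
#' @export
attach_demographics <- function(fv, demo) {
  need <- c("age", "weight", "height", "gender")
  if (is.data.frame(demo)) demo <- as.list(demo)
  miss <- setdiff(need, names(demo))
  if (length(miss) || any(vapply(demo[need], function(v) length(v) == 0 || is.na(v), TRUE)))
    stop("attach_demographics: missing demographic field(s): ",
         paste(c(miss, need[vapply(demo[need], function(v) length(v) == 0 || anyNA(v), TRUE)]), collapse = ","))
  if (any(need %in% names(fv)))
    stop("attach_demographics: feature vector already contains demographic keys")
  g <- demo$gender
  if (is.character(g)) g <- as.integer(tolower(substr(g, 1, 1)) == "m")
  c(fv, age = as.numeric(demo$age), weight = as.numeric(demo$weight),
    height = as.numeric(demo$height), gender = as.numeric(g))
}

#' Feature table of a preprocessed recording
#'
#' One row per gate-passing window: PWA features of the ensemble pulse plus,
#' if given, the subject demographics, alongside the window metadata and
#' reference BP (used downstream as calibration reference / ground truth).
#'
#' @param prep a `prep_recording` from [preprocess_recording()].
#' @param demographics optional 1-row data.frame for this subject.
#' @param ... passed to [pulse_features()].
#' @return data.frame; meta columns subject_id, window, start, sbp, dbp, mbp;
#'   remaining columns are features. Missing fiducials yield NA entries.
#' @export
extract_features <- function(prep, demographics = NULL, ...) {
  keep <- which(prep$windows$valid)
  if (!length(keep)) return(NULL)
  feat_names <- c("MAP", "MSBP", "MDBP", "ESP", "SPTI", "DPTI", "SEVR",
                  "PI", "AIx75", "HR", fiducial_names())
  rows <- lapply(keep, function(wi) {
    pulse <- prep$pulses[[wi]]
    # measure morphology from the pulse foot: the high-pass leaves the
    # ensemble pulse zero-mean, so re-zero it at its minimum
    pulse$waveform <- pulse$waveform - min(pulse$waveform)
    d <- pulse_derivatives(pulse)
    f <- detect_fiducials(d)
    fv <- pulse_features(pulse, d, f, dc = prep$windows$raw_mean[wi], ...)
    full <- setNames(rep(NA_real_, length(feat_names)), feat_names)
    full[intersect(names(fv), feat_names)] <- fv[intersect(names(fv), feat_names)]
    full
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  if (!is.null(demographics)) {
    out$age <- as.numeric(demographics$age)
    out$weight <- as.numeric(demographics$weight)
    out$height <- as.numeric(demographics$height)
    g <- demographics$gender
    if (is.character(g)) g <- as.integer(tolower(substr(g, 1, 1)) == "m")
    out$gender <- as.numeric(g)
  }
  meta <- data.frame(subject_id = prep$subject_id,
                     window = prep$windows$index[keep],
                     start = prep$windows$start[keep],
                     sbp = prep$windows$sbp[keep],
                     dbp = prep$windows$dbp[keep],
                     mbp = prep$windows$mbp[keep])
  cbind(meta, out)
}

# Columns of a feature table that are model features (not meta/targets).
feature_columns <- function(df) {
  setdiff(names(df), c("subject_id", "window", "start", "sbp", "dbp", "mbp"))
}
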