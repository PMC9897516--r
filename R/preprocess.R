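# Preprocessing: alignment, zero-phase band-pass filtering, 20-s windowing,
# beat segmentation, per-beat signal quality, quality-weighted ensemble
# averaging and windowed invasive reference values.

#' Zero-phase band-pass filtering of a PPG recording
#'
#' Cascade of a low-pass 3rd-order Butterworth (15 Hz, removes high-frequency
#' noise) and a high-pass 3rd-order Butterworth (0.5 Hz, removes the
#' baseline), both applied forward-backward so fiducial timing is not skewed
#' by group delay. The effective amplitude response is the squared magnitude
#' of each filter.
#'
#' @param sig a [waveform_recording()].
#' @param lp_cut,hp_cut cut-off frequencies in Hz.
#' @param order filter order (per pass).
#' @return filtered [waveform_recording()] (zero mean).
#' @export
bandpass_ppg <- function(sig, lp_cut = 15, hp_cut = 0.5, order = 3) {
  if (sig$fs <= 2 * lp_cut)
    stop("bandpass_ppg: fs must exceed twice the low-pass cut-off")
  b_lp <- signal::butter(order, lp_cut / (sig$fs / 2), type = "low")
  b_hp <- signal::butter(order, hp_cut / (sig$fs / 2), type = "high")
  # odd-reflection padding suppresses forward-backward edge transients, which
  # for a 0.5 Hz high-pass would otherwise bleed ~2 s into the record
  x <- sig$samples
  n <- length(x)
  P <- min(n - 1L, round(2 * sig$fs / hp_cut))
  if (P > 1L) {
    left <- 2 * x[1] - x[(P + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - P)]
    xp <- c(left, x, right)
  } else xp <- x
  y <- signal::filtfilt(b_hp, signal::filtfilt(b_lp, xp))
  if (P > 1L) y <- y[(P + 1L):(P + n)]
  out <- sig
  out$samples <- as.numeric(y)
  out
}

#' Time alignment of PPG and ABP by cross-correlation
#'
#' Both signals are band-pass filtered, centered, and cross-correlated; the
#' returned lag (seconds) maximizes the correlation. A positive lag means the
#' PPG lags the ABP by that amount, i.e. `ppg(t) ~ abp(t - lag)`; shifting the
#' PPG back by `lag` puts it on the ABP time base.
#'
#' @param ppg,abp [waveform_recording()]s at the same sampling rate.
#' @param max_lag maximum |lag| searched, in seconds.
#' @return lag in seconds.
#' @export
align_signals <- function(ppg, abp, max_lag = 2) {
  if (ppg$fs != abp$fs) stop("align_signals: signals must share a sampling rate")
  fs <- ppg$fs
  n <- min(length(ppg$samples), length(abp$samples))
  K <- floor(max_lag * fs)
  if (K >= n) stop("align_signals: max_lag exceeds the record length")
  x <- bandpass_ppg(abp)$samples[seq_len(n)]
  y <- bandpass_ppg(ppg)$samples[seq_len(n)]
  x <- x - mean(x); y <- y - mean(y)
  # cross-correlation via FFT: cc[k] = sum_t x[t] * y[t + k]
  m <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  Y <- stats::fft(c(y, numeric(m - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  lags <- -K:K
  vals <- cc[ifelse(lags >= 0, lags + 1L, m + lags + 1L)]
  lag <- lags[which.max(vals)] / fs
  overlap <- n - abs(lag) * fs
  if (overlap <= 0) stop("align_signals: empty overlap after shift")
  lag
}

#' Sliding analysis windows
#'
#' Windows of `win` seconds advancing by `win * (1 - overlap)`; only windows
#' fully contained in the record are returned, so a T-second record yields
#' floor((T - win)/stride) + 1 windows for T >= win, else none.
#'
#' @param sig_length_s record length in seconds.
#' @param win window length in seconds.
#' @param overlap fractional overlap in [0, 1).
#' @return data.frame with columns index, start, duration.
#' @export
make_windows <- function(sig_length_s, win = 20, overlap = 0.5) {
  stopifnot(win > 0, overlap >= 0, overlap < 1)
  stride <- win * (1 - overlap)
  if (sig_length_s < win)
    return(data.frame(index = integer(0), start = numeric(0), duration = numeric(0)))
  k <- 0:floor((sig_length_s - win) / stride)
  data.frame(index = k + 1L, start = k * stride, duration = win)
}

#' Beat onset (pulse foot) detection
#'
#' Slope-based foot detector for filtered PPG (also used on the ABP): local
#' maxima of the first derivative above an adaptive threshold locate systolic
#' upstrokes; the preceding local minimum of the signal (searched over 0.3 s)
#' is the pulse foot. A 0.24 s refractory period suppresses double firing.
#'
#' @param sig a [waveform_recording()] (band-passed PPG or raw ABP).
#' @return integer vector of onset sample indices (possibly empty).
#' @export
segment_beats <- function(sig) {
  x <- sig$samples
  fs <- sig$fs
  n <- length(x)
  if (n < fs) return(integer(0))
  v <- c(0, diff(x)) * fs
  pos <- v[v > 0]
  if (length(pos) < 10) return(integer(0))
  thr <- 0.4 * quantile(pos, 0.95, names = FALSE)
  if (thr <= 0) return(integer(0))
  ex <- local_extrema(v)
  up <- ex$idx[ex$type == "max" & v[ex$idx] > thr]
  if (length(up) == 0) return(integer(0))
  # refractory: among upstrokes closer than 0.24 s keep the steeper one
  refr <- round(0.24 * fs)
  keep <- integer(0)
  for (i in up) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (v[i] > v[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  # a foot cannot be located for an upstroke whose search window is cut off
  # by the start of the record
  keep <- keep[keep - round(0.3 * fs) >= 1]
  if (!length(keep)) return(integer(0))
  onsets <- vapply(keep, function(i) {
    j0 <- as.integer(i - round(0.3 * fs))
    j0 + which.min(x[j0:i]) - 1L
  }, integer(1))
  onsets <- sort(unique(onsets))
  # enforce physiologic inter-onset intervals
  if (length(onsets) > 1) {
    ibi <- diff(onsets) / fs
    onsets <- onsets[c(TRUE, ibi >= 0.24)]
  }
  onsets
}

#' Per-beat signal quality index
#'
#' Equal-weight mean of (a) the Pearson correlation of the beat with the
#' recording's template beat and (b) the mean Pearson correlation with its
#' neighboring beats, each mapped from [-1, 1] to [0, 1]. Zero-variance beats
#' score 0; with no neighbors only the template term is used.
#'
#' @param beat numeric vector (resampled to the common length).
#' @param template template beat of the recording (same length).
#' @param neighbors list of neighboring beats (same length).
#' @return SQI in [0, 1].
#' @export
beat_sqi <- function(beat, template, neighbors = list()) {
  r_t <- safe_cor(beat, template)
  if (is.na(r_t)) return(0)
  parts <- (r_t + 1) / 2
  if (length(neighbors)) {
    r_n <- vapply(neighbors, function(nb) safe_cor(beat, nb), numeric(1))
    r_n <- r_n[!is.na(r_n)]
    if (length(r_n)) parts <- c(parts, (mean(r_n) + 1) / 2)
  }
  mean(parts)
}

#' Quality-weighted ensemble-average pulse
#'
#' Onset-aligned beats (already resampled to a common length L) are averaged
#' with their SQIs as weights. The pulse heart rate is 60 over the median
#' inter-onset interval, and the pulse SQI is the SQI-weighted mean of the
#' beat SQIs.
#'
#' @param beats list of numeric beats or a beats-in-rows matrix.
#' @param sqis per-beat SQI vector.
#' @param L common beat length (beats are resampled if needed).
#' @param ibi inter-beat intervals in seconds (for heart rate).
#' @param window one row of [make_windows()] output (optional metadata).
#' @return list of class `ensemble_pulse`: waveform, fs_pulse, hr, sqi,
#'   valid, window.
#' @export
ensemble_average <- function(beats, sqis, L = 256, ibi = NULL, window = NULL) {
  if (is.matrix(beats)) beats <- asplit(beats, 1)
  stopifnot(length(beats) == length(sqis))
  mat <- t(vapply(beats, resample_to, numeric(L), L = L))
  w <- pmax(sqis, 0)
  hr <- if (!is.null(ibi) && length(ibi)) 60 / median(ibi) else NA_real_
  if (sum(w) == 0) {
    return(structure(list(waveform = rep(NA_real_, L), fs_pulse = NA_real_,
                          hr = hr, sqi = 0, valid = FALSE, window = window),
                     class = "ensemble_pulse"))
  }
  wf <- as.numeric(crossprod(mat, w) / sum(w))
  fs_pulse <- if (is.finite(hr)) L / (60 / hr) else NA_real_
  structure(list(waveform = wf, fs_pulse = fs_pulse, hr = hr,
                 sqi = weighted.mean(sqis, w), valid = all(is.finite(wf)),
                 window = window),
            class = "ensemble_pulse")
}

#' Windowed invasive reference blood pressure
#'
#' Beats are segmented on the ABP window; per-beat SBP/DBP/MBP are the beat
#' maximum/minimum/mean, window values are the medians of these series, and
#' the variability of each series is its standard deviation over its mean.
#'
#' @param abp_window numeric vector, mmHg.
#' @param fs sampling rate in Hz.
#' @return list of class `reference_bp`: sbp, dbp, mbp, var_sbp, var_dbp,
#'   n_beats, valid.
#' @export
reference_bp <- function(abp_window, fs) {
  invalid <- structure(list(sbp = NA_real_, dbp = NA_real_, mbp = NA_real_,
                            var_sbp = NA_real_, var_dbp = NA_real_,
                            n_beats = 0L, valid = FALSE),
                       class = "reference_bp")
  if (!all(is.finite(abp_window))) return(invalid)
  onsets <- segment_beats(waveform_recording(abp_window, fs, channel = "abp"))
  if (length(onsets) < 4L) return(invalid)  # >= 3 complete beats
  sbp_b <- dbp_b <- mbp_b <- numeric(length(onsets) - 1L)
  for (k in seq_len(length(onsets) - 1L)) {
    seg <- abp_window[onsets[k]:(onsets[k + 1L] - 1L)]
    sbp_b[k] <- max(seg); dbp_b[k] <- min(seg); mbp_b[k] <- mean(seg)
  }
  structure(list(sbp = median(sbp_b), dbp = median(dbp_b), mbp = median(mbp_b),
                 var_sbp = sd(sbp_b) / mean(sbp_b),
                 var_dbp = sd(dbp_b) / mean(dbp_b),
                 n_beats = length(sbp_b), valid = TRUE),
            class = "reference_bp")
}

#' Window exclusion gate
#'
#' A window is kept iff the ensemble-pulse SQI is at least `sqi_min` (75%)
#' and the reference variability (sd/mean of the per-beat series, checked for
#' both the SBP and DBP series) is at most `var_max` (10%).
#'
#' @param pulse an `ensemble_pulse`.
#' @param ref a `reference_bp` from the same window.
#' @param sqi_min minimum SQI.
#' @param var_max maximum reference variability.
#' @return TRUE to keep the window.
#' @export
gate_window <- function(pulse, ref, sqi_min = 0.75, var_max = 0.10) {
  isTRUE(pulse$valid) && isTRUE(ref$valid) &&
    is.finite(pulse$sqi) && pulse$sqi >= sqi_min &&
    is.finite(ref$var_sbp) && ref$var_sbp <= var_max &&
    is.finite(ref$var_dbp) && ref$var_dbp <= var_max
}

#' Preprocess one paired PPG/ABP recording
#'
#' Full first stage: cross-correlation alignment, zero-phase band-pass
#' filtering of the PPG, 20-s / 50%-overlap windowing, beat segmentation,
#' per-beat SQI against the recording's median-beat template and neighbors,
#' quality-weighted ensemble averaging, windowed median reference BP, and the
#' SQI/variability gate. The unfiltered PPG mean of each window is retained
#' as the DC term of the perfusion index.
#'
#' @param ppg,abp [waveform_recording()]s at a common sampling rate.
#' @param win,overlap windowing parameters (seconds, fraction).
#' @param L ensemble-pulse length in samples.
#' @param sqi_min,var_max gate thresholds, see [gate_window()].
#' @param lp_cut,hp_cut,order filter parameters, see [bandpass_ppg()].
#' @param max_lag alignment search range in seconds.
#' @return list of class `prep_recording`: `windows` (data.frame with gate
#'   decisions and reference BP per window) and `pulses` (list of
#'   `ensemble_pulse`).
#' @export
preprocess_recording <- function(ppg, abp, win = 20, overlap = 0.5, L = 256,
                                 sqi_min = 0.75, var_max = 0.10,
                                 lp_cut = 15, hp_cut = 0.5, order = 3,
                                 max_lag = 2) {
  stopifnot(ppg$fs == abp$fs)
  fs <- ppg$fs
  lag <- align_signals(ppg, abp, max_lag = max_lag)
  sh <- round(lag * fs)
  raw <- ppg$samples
  ab <- abp$samples
  if (sh > 0) raw <- raw[-seq_len(sh)] else if (sh < 0) ab <- ab[-seq_len(-sh)]
  n <- min(length(raw), length(ab))
  raw <- raw[seq_len(n)]; ab <- ab[seq_len(n)]
  fppg <- bandpass_ppg(waveform_recording(raw, fs, ppg$subject_id, "ppg"),
                       lp_cut, hp_cut, order)
  onsets <- segment_beats(fppg)
  wins <- make_windows(n / fs, win, overlap)
  nb <- length(onsets)
  beats_mat <- NULL
  if (nb >= 2) {
    beats_mat <- t(vapply(seq_len(nb - 1L), function(k) {
      resample_to(fppg$samples[onsets[k]:(onsets[k + 1L] - 1L)], L)
    }, numeric(L)))
    template <- apply(beats_mat, 2, median)
  }
  pulses <- vector("list", nrow(wins))
  rows <- vector("list", nrow(wins))
  for (wi in seq_len(nrow(wins))) {
    i0 <- floor(wins$start[wi] * fs) + 1L
    i1 <- min(floor((wins$start[wi] + win) * fs), n)
    ref <- reference_bp(ab[i0:i1], fs)
    in_win <- if (nb >= 2) which(onsets[-nb] >= i0 & onsets[-nb] < i1) else integer(0)
    if (length(in_win) >= 1 && !is.null(beats_mat)) {
      bm <- beats_mat[in_win, , drop = FALSE]
      sqis <- vapply(seq_along(in_win), function(j) {
        nbrs <- list()
        if (j > 1) nbrs <- c(nbrs, list(bm[j - 1, ]))
        if (j < length(in_win)) nbrs <- c(nbrs, list(bm[j + 1, ]))
        beat_sqi(bm[j, ], template, nbrs)
      }, numeric(1))
      ibi <- diff(onsets)[in_win] / fs
      pulse <- ensemble_average(bm, sqis, L = L, ibi = ibi,
                                window = wins[wi, ])
    } else {
      pulse <- ensemble_average(list(rep(0, L)), 0, L = L, window = wins[wi, ])
    }
    if (!all(is.finite(raw[i0:i1]))) pulse$valid <- FALSE
    pulses[[wi]] <- pulse
    rows[[wi]] <- data.frame(
      index = wins$index[wi], start = wins$start[wi],
      sbp = ref$sbp, dbp = ref$dbp, mbp = ref$mbp,
      var_sbp = ref$var_sbp, var_dbp = ref$var_dbp,
      sqi = pulse$sqi, hr = pulse$hr,
      raw_mean = mean(raw[i0:i1]),
      valid = gate_window(pulse, ref, sqi_min, var_max) &&
        is.finite(pulse$hr) && pulse$hr >= 20 && pulse$hr <= 250
    )
  }
  structure(list(subject_id = ppg$subject_id, lag = lag,
                 windows = do.call(rbind, rows), pulses = pulses),
            class = "prep_recording")
}
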