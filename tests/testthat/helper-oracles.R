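# Independent oracles used across tests: analytic two-Gaussian mixtures and
# their derivatives, the analytic Butterworth magnitude response, dense-grid
# extrema search, and simple constructed signals. These deliberately do not
# call the package's own implementations.

# two-Gaussian mixture and its first three analytic derivatives
gmix <- function(t, a1, c1, w1, a2, c2, w2) {
  a1 * exp(-(t - c1)^2 / (2 * w1^2)) + a2 * exp(-(t - c2)^2 / (2 * w2^2))
}
gmix_d1 <- function(t, a1, c1, w1, a2, c2, w2) {
  -a1 * (t - c1) / w1^2 * exp(-(t - c1)^2 / (2 * w1^2)) -
    a2 * (t - c2) / w2^2 * exp(-(t - c2)^2 / (2 * w2^2))
}
gmix_d2 <- function(t, a1, c1, w1, a2, c2, w2) {
  a1 / w1^2 * ((t - c1)^2 / w1^2 - 1) * exp(-(t - c1)^2 / (2 * w1^2)) +
    a2 / w2^2 * ((t - c2)^2 / w2^2 - 1) * exp(-(t - c2)^2 / (2 * w2^2))
}

# squared (zero-phase, forward-backward) cascaded Butterworth magnitude:
# |H_lp|^2 * |H_hp|^2 at frequency f for order-n low/high-pass cutoffs
butter_cascade_gain <- function(f, lp = 15, hp = 0.5, n = 3) {
  (1 / (1 + (f / lp)^(2 * n))) * ((f / hp)^(2 * n) / (1 + (f / hp)^(2 * n)))
}

# amplitude of a sinusoid at frequency f in signal y (complex demodulation
# over an interior stretch covering an integer number of cycles)
sine_amplitude <- function(y, fs, f, skip_s = 2) {
  n <- length(y)
  i0 <- round(skip_s * fs) + 1
  cycles <- floor((n - 2 * (i0 - 1)) / fs * f)
  stopifnot(cycles >= 1)
  i1 <- i0 + round(cycles * fs / f) - 1
  t <- (i0:i1 - 1) / fs
  2 * Mod(mean(y[i0:i1] * exp(-2i * pi * f * t)))
}

# dense-grid local extrema of a function (oracle for fiducial detection).
# min_prom applies the same published ripple rule as the detector: adjacent
# extrema pairs with an amplitude gap below the fraction of the signal range
# are discarded together.
grid_extrema <- function(fun, t0, t1, n = 200000, min_prom = 0) {
  t <- seq(t0, t1, length.out = n)
  v <- fun(t)
  d <- diff(v)
  up <- d[-length(d)] > 0 & d[-1] <= 0
  dn <- d[-length(d)] < 0 & d[-1] >= 0
  idx <- c(which(up), which(dn)) + 1
  ex <- data.frame(t = t[idx],
                   type = rep(c("max", "min"), c(sum(up), sum(dn))))
  ex <- ex[order(ex$t), ]
  if (min_prom > 0) {
    val <- fun(ex$t)
    thr <- min_prom * diff(range(v))
    while (nrow(ex) >= 2) {
      gaps <- abs(diff(val))
      m <- which.min(gaps)
      if (gaps[m] >= thr) break
      ex <- ex[-c(m, m + 1), ]; val <- val[-c(m, m + 1)]
    }
  }
  ex
}

# periodic pulse train from a fixed beat template function
pulse_train <- function(beat_fun, period, duration, fs) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  beat_fun(t %% period)
}

# standard small ensemble pulse for PWA tests: two-Gaussian, L samples
make_test_pulse <- function(a1 = 1, c1 = 0.15, w1 = 0.05, a2 = 0.4,
                            c2 = 0.40, w2 = 0.09, period = 0.8, L = 256,
                            hr = NULL) {
  t <- (seq_len(L) - 1) * period / L  # foot-to-foot, matching beat resampling
  structure(list(waveform = gmix(t, a1, c1, w1, a2, c2, w2),
                 fs_pulse = L / period,
                 hr = hr %||% 60 / period, sqi = 1, valid = TRUE,
                 window = NULL),
            class = "ensemble_pulse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny cohort configuration used by integration-style tests
small_cohort_config <- function(seed, n_subjects = 3,
                                duration_range = c(120, 180), ...) {
  cohort_config(n_subjects = n_subjects, duration_range = duration_range,
                seed = seed, ...)
}
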