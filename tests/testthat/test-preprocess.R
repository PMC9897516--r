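# Preprocessing: filtering, windowing, beat segmentation, SQI, ensemble
# averaging, reference BP and the exclusion gate.

test_that("window counts follow the stride arithmetic", {
  w <- make_windows(60)
  expect_equal(nrow(w), 5L)
  expect_equal(w$start, c(0, 10, 20, 30, 40))
  expect_equal(nrow(make_windows(20)), 1L)
  expect_equal(nrow(make_windows(19)), 0L)
  # formula floor((T - 20)/10) + 1 over random durations
  withr::with_seed(14, {
    for (T in runif(50, 0, 400)) {
      expected <- if (T >= 20) floor((T - 20) / 10) + 1 else 0
      expect_equal(nrow(make_windows(T)), expected, info = paste("T =", T))
    }
  })
})

test_that("band-pass filter matches the analytic cascaded Butterworth gain", {
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  # DC is removed (small IIR residual near the record edges tolerated)
  const <- waveform_recording(rep(3, length(t)), fs)
  expect_lt(max(abs(bandpass_ppg(const)$samples)), 1e-3)
  expect_lt(abs(mean(bandpass_ppg(const)$samples)), 1e-4)
  # passband sine at 2 Hz keeps (almost) its amplitude
  s2 <- bandpass_ppg(waveform_recording(sin(2 * pi * 2 * t), fs))
  a2 <- sine_amplitude(s2$samples, fs, 2)
  expect_gt(a2, 0.95); expect_lte(a2, 1.0 + 1e-6)
  # deep-stopband sine at 0.05 Hz is suppressed
  s005 <- bandpass_ppg(waveform_recording(sin(2 * pi * 0.05 * t), fs))
  expect_lt(sine_amplitude(s005$samples, fs, 0.05, skip_s = 10), 0.01)
  # measured gains match |H_lp|^2 |H_hp|^2 at probe frequencies
  for (f in c(1, 2, 4, 8)) {
    y <- bandpass_ppg(waveform_recording(sin(2 * pi * f * t), fs))
    expect_equal(sine_amplitude(y$samples, fs, f),
                 butter_cascade_gain(f), tolerance = 0.01)
  }
  # linearity: bandpass(a x) = a bandpass(x)
  x <- withr::with_seed(3, rnorm(5000))
  y1 <- bandpass_ppg(waveform_recording(7.5 * x, fs))$samples
  y2 <- 7.5 * bandpass_ppg(waveform_recording(x, fs))$samples
  expect_lt(max(abs(y1 - y2)) / max(abs(y2)), 1e-9)
  expect_error(bandpass_ppg(waveform_recording(x, fs = 25)), "twice")
})

test_that("cross-correlation alignment recovers known lags", {
  fs <- 100
  beat <- function(tau) gmix(tau, 1, 0.15, 0.05, 0.4, 0.4, 0.09)
  x <- pulse_train(beat, period = 0.8, duration = 30, fs = fs)
  ref <- waveform_recording(100 + 20 * x, fs, channel = "abp")
  # identical signals
  expect_equal(align_signals(waveform_recording(x, fs), ref), 0)
  # exact half-second delay of the PPG (search kept below the beat period to
  # avoid the periodicity alias of a perfectly regular train)
  k <- round(0.5 * fs)
  delayed <- waveform_recording(c(rep(x[1], k), x[1:(length(x) - k)]), fs)
  expect_equal(align_signals(delayed, ref, max_lag = 0.7), 0.5)
  # noisy 0.2 s offset (SNR 10 dB), checked against brute-force correlation
  k2 <- round(0.2 * fs)
  noisy <- withr::with_seed(11, {
    y <- c(rep(x[1], k2), x[1:(length(x) - k2)])
    y + rnorm(length(y), 0, sd(y) / sqrt(10))
  })
  got <- align_signals(waveform_recording(noisy, fs), ref, max_lag = 0.5)
  # brute-force oracle over all integer lags
  xr <- 100 + 20 * x
  K <- round(0.5 * fs)
  brute <- sapply(-K:K, function(L) {
    if (L >= 0) cor(xr[1:(length(x) - L)], noisy[(1 + L):length(x)])
    else cor(xr[(1 - L):length(x)], noisy[1:(length(x) + L)])
  })
  oracle <- (-K:K)[which.max(brute)] / fs
  expect_equal(got, oracle, tolerance = 1 / fs + 1e-9)
  expect_lte(abs(got - 0.2), 1 / fs + 1e-9)
  expect_error(align_signals(waveform_recording(x[1:50], fs),
                             waveform_recording(x[1:50], fs, channel = "abp"),
                             max_lag = 10), "max_lag")
})

test_that("beat segmentation finds pulse feet of a periodic train", {
  fs <- 125
  beat <- function(tau) gmix(tau, 1, 0.15, 0.05, 0.4, 0.4, 0.09)
  x <- pulse_train(beat, period = 1.0, duration = 20, fs = fs)
  sig <- bandpass_ppg(waveform_recording(x, fs))
  onsets <- segment_beats(sig)
  expect_gte(length(onsets), 19L)
  expect_lte(length(onsets), 21L)
  ibi <- diff(onsets) / fs
  expect_true(all(abs(ibi - 1.0) < 0.02))
  # flat signal: no beats
  expect_length(segment_beats(waveform_recording(rep(1, 1000), fs)), 0L)
})

test_that("beat SQI honors template and neighbor similarity", {
  beat <- gmix(seq(0, 0.8, length.out = 128), 1, 0.15, 0.05, 0.4, 0.4, 0.09)
  expect_equal(beat_sqi(beat, beat, list(beat, beat)), 1)
  expect_equal(beat_sqi(-beat, beat, list(beat)), 0)
  expect_equal(beat_sqi(rep(2, 128), beat), 0)  # zero variance
  # strictly decreasing in noise level over 5 seeded SNR steps
  sqis <- withr::with_seed(8, vapply(c(30, 20, 10, 5, 0), function(snr) {
    noisy <- beat + rnorm(128, 0, sd(beat) / 10^(snr / 20))
    beat_sqi(noisy, beat, list(beat))
  }, numeric(1)))
  expect_true(all(diff(sqis) < 0))
})

test_that("ensemble averaging is a weighted mean with the stated invariances", {
  L <- 64
  b1 <- sin(seq(0, pi, length.out = L))
  b2 <- b1^2
  b3 <- sqrt(b1)
  # idempotent on identical beats
  ea <- ensemble_average(list(b1, b1, b1), c(0.9, 0.8, 1), L = L, ibi = rep(1, 3))
  expect_equal(ea$waveform, b1)
  expect_equal(ea$hr, 60)
  # zero-weight beats are excluded
  ea2 <- ensemble_average(list(b1, b2), c(1, 0), L = L)
  expect_equal(ea2$waveform, b1)
  # hand-computed weighted mean
  ea3 <- ensemble_average(list(b1, b2, b3), c(0.5, 0.25, 0.25), L = L)
  expect_equal(ea3$waveform, (0.5 * b1 + 0.25 * b2 + 0.25 * b3) / 1)
  # invariant to beat ordering
  ea4 <- ensemble_average(list(b3, b1, b2), c(0.25, 0.5, 0.25), L = L)
  expect_equal(ea4$waveform, ea3$waveform)
  # all-zero SQI gives an invalid pulse
  expect_false(ensemble_average(list(b1), 0, L = L)$valid)
})

test_that("window gate applies the 75% SQI and 10% variability thresholds exactly", {
  mk_pulse <- function(sqi) structure(list(sqi = sqi, valid = TRUE),
                                      class = "ensemble_pulse")
  mk_ref <- function(v_s, v_d = v_s) structure(
    list(var_sbp = v_s, var_dbp = v_d, valid = TRUE), class = "reference_bp")
  expect_true(gate_window(mk_pulse(0.80), mk_ref(0.05)))
  expect_false(gate_window(mk_pulse(0.74), mk_ref(0.05)))
  expect_false(gate_window(mk_pulse(0.90), mk_ref(0.11)))
  expect_true(gate_window(mk_pulse(0.75), mk_ref(0.10)))   # boundaries inclusive
  expect_false(gate_window(mk_pulse(0.90), mk_ref(0.05, 0.11)))  # both series gated
  # monotone: raising SQI never flips keep -> drop; raising variability never
  # flips drop -> keep
  withr::with_seed(21, {
    for (i in 1:50) {
      s <- runif(1); v <- runif(1, 0, 0.3)
      g <- gate_window(mk_pulse(s), mk_ref(v))
      if (g) expect_true(gate_window(mk_pulse(min(s + runif(1), 1)), mk_ref(v)))
      else expect_false(gate_window(mk_pulse(s), mk_ref(v + runif(1))))
    }
  })
})

test_that("windowed reference BP takes per-beat medians", {
  fs <- 125
  tpl <- function(tau) gmix(tau, 1, 0.15, 0.05, 0.4, 0.4, 0.09)
  period <- 0.8
  render <- function(sbps, dbp = 60) {
    tau <- seq(0, period - 1 / fs, by = 1 / fs)
    b <- tpl(tau); bn <- (b - min(b)) / (max(b) - min(b))
    unlist(lapply(sbps, function(s) dbp + (s - dbp) * bn))
  }
  # fixed-amplitude train: window SBP/DBP equal the construction exactly
  x <- render(rep(120, 25))
  ref <- reference_bp(x, fs)
  expect_true(ref$valid)
  expect_equal(ref$sbp, 120, tolerance = 1e-6)
  expect_equal(ref$dbp, 60, tolerance = 1e-6)
  expect_true(ref$dbp <= ref$mbp && ref$mbp <= ref$sbp)
  # median of a varying per-beat SBP series
  ref2 <- reference_bp(render(rep(c(110, 120, 130), 8)), fs)
  expect_equal(ref2$sbp, 120, tolerance = 0.5)
  # drifting amplitude: variability equals sd/mean of the measured beat
  # maxima (the detector sees complete interior beats: the first foot lies in
  # a truncated search window and the final beat has no closing onset)
  sbps <- seq(100, 140, length.out = 24)
  ref3 <- reference_bp(render(sbps), fs)
  expect_equal(ref3$n_beats, 22)
  expect_equal(ref3$var_sbp, sd(sbps[2:23]) / mean(sbps[2:23]),
               tolerance = 0.02)
  # too few beats
  expect_false(reference_bp(render(rep(120, 2)), fs)$valid)
})

test_that("preprocessing a synthetic recording yields gated windows with sane references", {
  cfg <- small_cohort_config(seed = 404, n_subjects = 1,
                             duration_range = c(150, 150))
  r <- synth_recording(cfg, 77L, "s1")
  prep <- preprocess_recording(r$ppg, r$abp)
  w <- prep$windows
  expect_equal(nrow(w), floor((150 - 20) / 10) + 1)
  expect_gt(sum(w$valid), 0)
  ok <- w[w$valid, ]
  expect_true(all(ok$dbp < ok$mbp & ok$mbp < ok$sbp))
  expect_true(all(ok$sqi >= 0.75))
  expect_true(all(ok$hr > 20 & ok$hr < 250))
  # window references track the commanded trajectory
  tr <- r$trajectory
  cmd <- approx(tr$t, tr$sbp, xout = ok$start + 10)$y
  expect_lt(median(abs(ok$sbp - cmd)), 5)
})
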