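# Pulse wave analysis: derivatives, fiducial detection against analytic
# oracles, morphological features and their invariances.

test_that("derivatives match closed forms", {
  L <- 512; dur <- 1
  t <- seq(0, dur, length.out = L)
  fs <- L / dur
  # sine: vpg ~ 2*pi*cos
  d <- pulse_derivatives(sin(2 * pi * t), fs_pulse = fs)
  interior <- 20:(L - 20)
  expect_lt(max(abs(d$vpg[interior] - 2 * pi * cos(2 * pi * t[interior]))),
            0.01 * 2 * pi)
  # quadratic: apg ~ 2, jpg ~ 0
  d2 <- pulse_derivatives(t^2, fs_pulse = fs)
  expect_lt(max(abs(d2$apg[interior] - 2)), 0.02)
  expect_lt(max(abs(d2$jpg[interior])), 1)  # ~0 vs the apg level of 2
  # two-Gaussian pulse: vpg matches the analytic mixture derivative
  pars <- list(a1 = 1, c1 = 0.15, w1 = 0.05, a2 = 0.4, c2 = 0.40, w2 = 0.09)
  p <- make_test_pulse(pars$a1, pars$c1, pars$w1, pars$a2, pars$c2, pars$w2,
                       period = 0.8, L = 256)
  dv <- pulse_derivatives(p)
  tt <- (seq_len(256) - 1) / p$fs_pulse
  truth <- gmix_d1(tt, pars$a1, pars$c1, pars$w1, pars$a2, pars$c2, pars$w2)
  i2 <- 10:246
  rmse <- sqrt(mean((dv$vpg[i2] - truth[i2])^2))
  expect_lt(rmse, 0.01 * max(abs(truth)))
  expect_error(pulse_derivatives(1:10, fs_pulse = 10), "too short")
})

test_that("fiducial detection matches dense-grid analytic extrema", {
  # systolic / diastolic peaks of the standard two-Gaussian pulse
  p <- make_test_pulse()
  d <- pulse_derivatives(p)
  f <- detect_fiducials(d)
  ex0 <- grid_extrema(function(t) gmix(t, 1, 0.15, 0.05, 0.4, 0.40, 0.09),
                      0, 0.8)
  peaks <- ex0$t[ex0$type == "max"]
  expect_lt(abs(f$ppg.sys_peak[["t"]] - peaks[1]), 0.010)
  expect_lt(abs(f$ppg.dia_peak[["t"]] - peaks[2]), 0.010)
  expect_lt(abs(peaks[1] - 0.15), 0.005)
  expect_lt(abs(peaks[2] - 0.40), 0.005)
  # APG a-e against analytic second-derivative extrema (same selection rule:
  # first local max, then alternating), within 1 sample
  ex2 <- grid_extrema(function(t) gmix_d2(t, 1, 0.15, 0.05, 0.4, 0.40, 0.09),
                      0, 0.8)
  a_row <- which(ex2$type == "max")[1]
  truth_t <- ex2$t[a_row:(a_row + 4)]
  got_t <- vapply(paste0("apg.", letters[1:5]), function(nm) f[[nm]][["t"]],
                  numeric(1))
  expect_true(all(abs(got_t - truth_t) <= 1 / p$fs_pulse + 1e-9))
  # fiducial times are strictly ordered within each derivative sequence
  expect_true(all(diff(got_t) > 0))
  # degenerate single-Gaussian pulse: no diastolic wave detected
  p1 <- make_test_pulse(a2 = 0)
  f1 <- detect_fiducials(pulse_derivatives(p1))
  expect_null(f1$ppg.dia_peak)
})

test_that("fiducials track analytic extrema across random pulse shapes", {
  withr::with_seed(99, {
    for (i in 1:10) {
      a2 <- runif(1, 0.25, 0.7); c2 <- runif(1, 0.38, 0.52)
      w1 <- runif(1, 0.04, 0.07); period <- runif(1, 0.6, 1.1)
      p <- make_test_pulse(1, 0.15, w1, a2, c2, 0.09, period = period)
      f <- detect_fiducials(pulse_derivatives(p))
      ex0 <- grid_extrema(function(t) gmix(t, 1, 0.15, w1, a2, c2, 0.09),
                          0, period, n = 50000)
      peaks <- ex0$t[ex0$type == "max"]
      expect_lt(abs(f$ppg.sys_peak[["t"]] - peaks[1]), 2 / p$fs_pulse)
      if (length(peaks) >= 2 && !is.null(f$ppg.dia_peak))
        expect_lt(abs(f$ppg.dia_peak[["t"]] - peaks[2]), 2 / p$fs_pulse)
    }
  })
})

test_that("features of elementary pulses equal hand-computed values", {
  # constant-height rectangle: areas of a rectangle
  L <- 1001
  pulse <- structure(list(waveform = rep(1, L), fs_pulse = 1000, hr = 60,
                          sqi = 1, valid = TRUE), class = "ensemble_pulse")
  f <- structure(list(ppg.dicrotic_notch = c(t = 0.35, a = 1)),
                 class = "fiducial_set")
  d <- list(ppg = pulse$waveform)
  fv <- pulse_features(pulse, d, f)
  expect_equal(fv[["MAP"]], 1)
  expect_equal(fv[["ESP"]], 1)
  expect_equal(fv[["SPTI"]], 0.35)
  expect_equal(fv[["DPTI"]], 0.65)
  expect_equal(fv[["SEVR"]], 0.65 / 0.35)
  # pure sine of amplitude 1 on a DC of 10: PI = 10%
  t <- seq(0, 1, length.out = 512)
  ps <- structure(list(waveform = sin(2 * pi * t), fs_pulse = 512, hr = 60,
                       sqi = 1, valid = TRUE), class = "ensemble_pulse")
  fv2 <- pulse_features(ps, list(ppg = ps$waveform),
                        structure(list(), class = "fiducial_set"), dc = 10)
  expect_equal(fv2[["PI"]], 10, tolerance = 1e-3)
  # two-Gaussian pulse: MAP / SPTI / DPTI match high-resolution quadrature
  p <- make_test_pulse()
  dv <- pulse_derivatives(p)
  fid <- detect_fiducials(dv)
  fv3 <- pulse_features(p, dv, fid)
  tn <- fid$ppg.dicrotic_notch[["t"]]
  qfun <- function(lo, hi) stats::integrate(function(t)
    gmix(t, 1, 0.15, 0.05, 0.4, 0.40, 0.09), lo, hi,
    rel.tol = 1e-10)$value
  expect_equal(fv3[["SPTI"]], qfun(0, tn), tolerance = 0.005)
  expect_equal(fv3[["DPTI"]], qfun(tn, 0.8), tolerance = 0.005)
  expect_equal(fv3[["MAP"]], qfun(0, 0.8) / 0.8, tolerance = 0.005)
})

test_that("SPTI/DPTI conservation and SEVR identity hold", {
  p <- make_test_pulse()
  dv <- pulse_derivatives(p)
  fid <- detect_fiducials(dv)
  fv <- pulse_features(p, dv, fid)
  t <- (seq_len(256) - 1) / p$fs_pulse
  total <- sum(diff(t) * (p$waveform[-1] + p$waveform[-256])) / 2
  expect_equal(fv[["SPTI"]] + fv[["DPTI"]], total, tolerance = 1e-6)
  expect_equal(fv[["SEVR"]] * fv[["SPTI"]], fv[["DPTI"]])
})

test_that("time shift moves fiducials; positive scaling acts as expected", {
  shift <- 0.08
  p0 <- make_test_pulse(c1 = 0.15, c2 = 0.40)
  p1 <- make_test_pulse(c1 = 0.15 + shift, c2 = 0.40 + shift)
  f0 <- detect_fiducials(pulse_derivatives(p0))
  f1 <- detect_fiducials(pulse_derivatives(p1))
  common <- intersect(names(f0), names(f1))
  expect_gt(length(common), 8)
  for (nm in setdiff(common, "vpg.w")) {
    expect_equal(f1[[nm]][["t"]] - f0[[nm]][["t"]], shift,
                 tolerance = 0.08, info = nm)
    expect_equal(f1[[nm]][["a"]], f0[[nm]][["a"]], tolerance = 0.05,
                 info = nm)
  }
  # scaling by c > 0: areas and levels scale; SEVR and AIx75 invariant
  cscale <- 3.7
  ps <- p0; ps$waveform <- cscale * p0$waveform
  dv0 <- pulse_derivatives(p0); dvs <- pulse_derivatives(ps)
  fv0 <- pulse_features(p0, dv0, detect_fiducials(dv0))
  fvs <- pulse_features(ps, dvs, detect_fiducials(dvs))
  for (nm in c("MAP", "MSBP", "MDBP", "ESP", "SPTI", "DPTI"))
    expect_equal(fvs[[nm]], cscale * fv0[[nm]], tolerance = 1e-9, info = nm)
  expect_equal(fvs[["SEVR"]], fv0[["SEVR"]], tolerance = 1e-9)
  expect_equal(fvs[["AIx75"]], fv0[["AIx75"]], tolerance = 1e-9)
})

test_that("demographics are appended strictly", {
  fv <- c(MAP = 1, HR = 60)
  out <- attach_demographics(fv, list(age = 62, weight = 72, height = 170,
                                      gender = "m"))
  expect_length(out, length(fv) + 4L)
  expect_equal(out[["gender"]], 1)
  expect_error(attach_demographics(out, list(age = 62, weight = 72,
                                             height = 170, gender = 1)),
               "already contains")
  expect_error(attach_demographics(fv, list(age = 62, weight = 72,
                                            height = 170)), "missing")
  expect_error(attach_demographics(fv, list()), "missing")
})
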