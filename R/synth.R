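# Synthetic cohort generator: paired PPG/ABP recordings with
# anesthesia-induction style blood-pressure swings and a documented,
# closed-form morphology-BP link so downstream feature selection and
# regression have a known ground truth.

#' Configuration of a synthetic cohort
#'
#' Defaults emulate an anesthesia-induction cohort: 40 adult subjects,
#' 9-19 minute recordings, per-subject mean SBP drawn from N(124.3, 24.8^2)
#' truncated to (90, 195) mmHg, per-subject mean DBP around 63 +/- 10 mmHg,
#' and an induction drop of 20-45% of baseline over 1-3 minutes followed by
#' partial, bumpy recovery plus slow AR(1) drift.
#'
#' @param n_subjects number of subjects.
#' @param fs sampling rate in Hz for both channels.
#' @param duration_range recording length range in seconds.
#' @param sbp_mean,sbp_sd,sbp_trunc cohort distribution of per-subject mean
#'   SBP (mmHg): normal mean/sd and truncation range.
#' @param dbp_mean,dbp_sd cohort distribution of per-subject mean DBP (mmHg).
#' @param drop_frac_range relative induction drop (fraction of baseline).
#' @param drop_onset_range,drop_duration_range timing of the drop (s).
#' @param recovery_frac fraction of the drop recovered after the nadir.
#' @param ar_sd standard deviation of the slow AR(1) BP drift (mmHg).
#' @param hr_range resting heart-rate range (bpm).
#' @param noise_sd additive white-noise sd on the PPG, as a fraction of the
#'   systolic pulse amplitude.
#' @param abp_noise_sd additive noise on the ABP (mmHg).
#' @param wander_amp amplitude of the respiratory baseline wander added to
#'   the PPG (same units as the pulse).
#' @param corruption_frac fraction of PPG beats replaced by noise bursts
#'   (exercises the SQI gate).
#' @param gain_sd per-subject PPG gain sd (multiplicative, around 1).
#' @param dc_range per-subject PPG DC offset range (arbitrary units).
#' @param morph_offset_sd per-subject offset sd on the diastolic-wave
#'   amplitude ratio (the nuisance a calibration measure corrects).
#' @param timing_offset_sd per-subject offset sd on the diastolic-wave
#'   timing, as a fraction of the beat period.
#' @param seed mandatory integer seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 40, fs = 125,
                          duration_range = c(540, 1140),
                          sbp_mean = 124.3, sbp_sd = 24.8, sbp_trunc = c(90, 195),
                          dbp_mean = 63.0, dbp_sd = 10.4,
                          drop_frac_range = c(0.20, 0.45),
                          drop_onset_range = c(60, 180),
                          drop_duration_range = c(60, 180),
                          recovery_frac = 0.55,
                          ar_sd = 3,
                          hr_range = c(55, 90),
                          noise_sd = 0.02,
                          abp_noise_sd = 0.2,
                          wander_amp = 0.08,
                          corruption_frac = 0.02,
                          gain_sd = 0.08,
                          dc_range = c(3, 6),
                          morph_offset_sd = 0.06,
                          timing_offset_sd = 0.015,
                          seed) {
  if (missing(seed)) stop("cohort_config: seed is mandatory")
  cfg <- as.list(environment())
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (fs <= 40) stop("fs too low for pulse morphology")
  structure(cfg, class = "cohort_config")
}

# Smooth logistic step from 0 to 1 centered at t0 with 10-90% width w.
logistic_step <- function(t, t0, w) 1 / (1 + exp(-4.39 * (t - t0) / w))

#' Blood-pressure trajectory of one synthetic subject
#'
#' Piecewise-smooth trajectory on a 1-s grid: baseline plateau, logistic
#' induction drop, partial recovery with vasopressor-like bumps, and a slow
#' AR(1) drift. The plateau level is scaled so the per-subject time mean
#' (drift aside) equals the drawn target mean, and the nadir sits at exactly
#' plateau * (1 - drop fraction).
#'
#' @param cfg a [cohort_config()].
#' @param subject_seed integer seed for this subject.
#' @param duration_s recording length; drawn from `cfg$duration_range` if NULL.
#' @return data.frame with columns t (s), sbp, dbp (mmHg), hr (bpm).
#' @export
bp_trajectory <- function(cfg, subject_seed, duration_s = NULL) {
  withr::with_seed(subject_seed, {
    dur <- duration_s %||% runif(1, cfg$duration_range[1], cfg$duration_range[2])
    t <- seq(0, dur, by = 1)
    m_sbp <- clip(rnorm(1, cfg$sbp_mean, cfg$sbp_sd), cfg$sbp_trunc[1], cfg$sbp_trunc[2])
    m_dbp <- clip(0.42 * m_sbp + rnorm(1, 10.8, 5), 43, 87)
    f <- runif(1, cfg$drop_frac_range[1], cfg$drop_frac_range[2])
    t_on <- runif(1, cfg$drop_onset_range[1], cfg$drop_onset_range[2])
    w <- runif(1, cfg$drop_duration_range[1], cfg$drop_duration_range[2])
    # unit shape: 0 at baseline, -1 at nadir, partial recovery with bumps;
    # recovery and bumps are kept clear of the nadir so the configured drop
    # fraction is actually realized
    shape <- -logistic_step(t, t_on + w / 2, w)
    w_rec <- runif(1, 60, 180)
    t_rec <- t_on + 1.5 * w + w_rec  # nadir dwell before recovery
    shape <- shape + cfg$recovery_frac * logistic_step(t, t_rec, w_rec)
    n_bump <- sample(0:2, 1)
    if (n_bump > 0) {
      for (b in seq_len(n_bump)) {
        sb <- runif(1, 20, 60)
        tb <- runif(1, t_rec + 2 * sb, max(t_rec + 2 * sb + 1, dur))
        shape <- shape + runif(1, 0.05, 0.25) * exp(-(t - tb)^2 / (2 * sb^2))
      }
    }
    shape <- clip(shape, -1, 0.15)
    ar <- as.numeric(stats::filter(rnorm(length(t), 0, cfg$ar_sd * sqrt(1 - 0.98^2)),
                                   0.98, method = "recursive"))
    # plateau baseline b chosen so the time mean equals the drawn target mean;
    # the nadir then sits at exactly b * (1 - f)
    b_sbp <- m_sbp / (1 + f * mean(shape))
    sbp <- b_sbp * (1 + f * shape) + ar
    b_dbp <- m_dbp / (1 + 0.75 * f * mean(shape))
    dbp <- b_dbp * (1 + 0.75 * f * shape) + 0.6 * ar
    dbp <- pmin(dbp, sbp - 12)
    sbp <- pmax(sbp, 60); dbp <- pmax(dbp, 30)
    hr0 <- runif(1, cfg$hr_range[1], cfg$hr_range[2])
    hr <- clip(hr0 - 8 * shape + 0.3 * ar, 45, 115)
    data.frame(t = t, sbp = sbp, dbp = dbp, hr = hr)
  })
}

#' Map a blood-pressure state to two-Gaussian pulse parameters
#'
#' The documented ground-truth link the pipeline must recover. With
#' s = (SBP - 120)/25 and d = (DBP - 65)/10 and beat period T = 60/HR:
#' systolic Gaussian at 0.16 T with width (0.065 - 0.006 d) T and unit
#' amplitude; diastolic (reflected) Gaussian at (0.47 - 0.03 s) T with width
#' 0.11 T and amplitude 0.30 + 0.09 s. Higher SBP therefore gives an earlier
#' and larger reflected wave; higher DBP a narrower systolic upstroke. The
#' timing slope is kept gentle so the reflected wave never merges into the
#' systolic Gaussian and the planted amplitude link stays globally linear
#' over the physiologic range. Deterministic: identical inputs give
#' identical parameters.
#'
#' @param sbp,dbp blood pressure in mmHg.
#' @param hr heart rate in bpm.
#' @return list with fields sys_center, sys_width, sys_amp, dia_center,
#'   dia_width, dia_amp, baseline, period (times in seconds).
#' @export
pulse_from_bp <- function(sbp, dbp, hr) {
  T <- 60 / hr
  s <- (sbp - 120) / 25
  d <- (dbp - 65) / 10
  list(
    sys_center = 0.16 * T,
    sys_width  = clip(0.065 - 0.006 * d, 0.035, 0.10) * T,
    sys_amp    = 1,
    dia_center = clip(0.47 - 0.03 * s, 0.33, 0.58) * T,
    dia_width  = 0.11 * T,
    dia_amp    = clip(0.30 + 0.09 * s, 0.05, 0.85),
    baseline   = 0,
    period     = T
  )
}

#' Evaluate a two-Gaussian pulse template
#'
#' @param t time points in seconds (0 = pulse foot).
#' @param p parameter list as returned by [pulse_from_bp()].
#' @return numeric vector of pulse values.
#' @export
two_gaussian_pulse <- function(t, p) {
  p$baseline +
    p$sys_amp * exp(-(t - p$sys_center)^2 / (2 * p$sys_width^2)) +
    p$dia_amp * exp(-(t - p$dia_center)^2 / (2 * p$dia_width^2))
}

#' Render one synthetic paired PPG/ABP recording
#'
#' Beats are rendered sequentially from the subject's BP trajectory via
#' [pulse_from_bp()]. The PPG gets a per-subject gain, DC offset and
#' morphology nuisance offsets, respiratory baseline wander, additive white
#' noise, and a configurable fraction of corrupted (noise-burst) beats. The
#' ABP is the same template rescaled per beat so its maximum/minimum equal
#' the commanded SBP/DBP exactly before noise.
#'
#' @param cfg a [cohort_config()].
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier stored on the recordings.
#' @return list with elements ppg, abp ([waveform_recording()]s),
#'   demographics (1-row data.frame), trajectory (ground truth), and
#'   subject_effects (the drawn nuisance offsets).
#' @export
synth_recording <- function(cfg, subject_seed, subject_id = "s1") {
  traj <- bp_trajectory(cfg, subject_seed)
  withr::with_seed(derive_seed(subject_seed, 1L), {
    dur <- max(traj$t)
    fs <- cfg$fs
    gain <- clip(rnorm(1, 1, cfg$gain_sd), 0.6, 1.4)
    dc <- runif(1, cfg$dc_range[1], cfg$dc_range[2])
    a2_off <- rnorm(1, 0, cfg$morph_offset_sd)
    c2_off <- rnorm(1, 0, cfg$timing_offset_sd)
    n <- floor(dur * fs)
    ppg <- numeric(n); abp <- numeric(n)
    tt <- (seq_len(n) - 1) / fs
    t_beat <- 0
    while (TRUE) {
      k <- findInterval(t_beat, traj$t)
      sbp <- traj$sbp[k]; dbp <- traj$dbp[k]; hr <- traj$hr[k]
      T <- 60 / hr * (1 + rnorm(1, 0, 0.01))
      i0 <- floor(t_beat * fs) + 1L
      i1 <- min(floor((t_beat + T) * fs), n)
      if (i1 < i0 || i0 > n) break
      idx <- i0:i1
      tau <- tt[idx] - t_beat
      p <- pulse_from_bp(sbp, dbp, hr)
      p$dia_amp <- clip(p$dia_amp + a2_off, 0.03, 0.95)
      p$dia_center <- p$dia_center + c2_off * p$period
      beat <- two_gaussian_pulse(tau, p)
      if (runif(1) < cfg$corruption_frac) {
        ppg[idx] <- gain * rnorm(length(idx), 0, 0.5)
      } else {
        ppg[idx] <- gain * beat
      }
      bn <- beat - min(beat)
      bn <- if (max(bn) > 0) bn / max(bn) else bn
      abp[idx] <- dbp + (sbp - dbp) * bn
      t_beat <- t_beat + T
      if (t_beat >= dur) break
    }
    wander <- cfg$wander_amp * gain * sin(2 * pi * 0.15 * tt + runif(1, 0, 2 * pi))
    ppg <- ppg + dc + wander + rnorm(n, 0, cfg$noise_sd * gain)
    if (cfg$abp_noise_sd > 0) abp <- abp + rnorm(n, 0, cfg$abp_noise_sd)
    demo <- data.frame(
      subject_id = subject_id,
      age = round(clip(rnorm(1, 62.4, 12.7), 27, 81)),
      weight = round(clip(rnorm(1, 72.6, 13.4), 46, 102), 1),
      height = round(clip(rnorm(1, 170.1, 9.9), 154, 189), 1),
      gender = rbinom(1, 1, 0.525),
      stringsAsFactors = FALSE
    )
    list(
      ppg = waveform_recording(ppg, fs, subject_id, "ppg"),
      abp = waveform_recording(abp, fs, subject_id, "abp"),
      demographics = demo,
      trajectory = traj,
      subject_effects = list(gain = gain, dc = dc, a2_offset = a2_off,
                             c2_offset = c2_off)
    )
  })
}

#' Generate a full synthetic cohort
#'
#' Bit-reproducible given the config (subject seeds are derived from
#' `cfg$seed`).
#'
#' @param cfg a [cohort_config()].
#' @return list with `recordings` (list per subject), `demographics`
#'   (data.frame) and the config.
#' @export
synth_cohort <- function(cfg) {
  ids <- sprintf("s%02d", seq_len(cfg$n_subjects))
  recs <- vector("list", cfg$n_subjects)
  names(recs) <- ids
  for (i in seq_len(cfg$n_subjects)) {
    recs[[i]] <- synth_recording(cfg, derive_seed(cfg$seed, i), ids[i])
  }
  demo <- do.call(rbind, lapply(recs, `[[`, "demographics"))
  rownames(demo) <- NULL
  list(recordings = recs, demographics = demo, config = cfg)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' Layout: `<id>_ppg.csv`, `<id>_abp.csv` (time_s,value) plus
#' `demographics.csv` and a ground-truth `trajectories.csv`.
#'
#' @param cohort result of [synth_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    r <- cohort$recordings[[id]]
    write_waveform_csv(r$ppg, file.path(dir, paste0(id, "_ppg.csv")))
    write_waveform_csv(r$abp, file.path(dir, paste0(id, "_abp.csv")))
  }
  utils::write.csv(cohort$demographics, file.path(dir, "demographics.csv"),
                   row.names = FALSE)
  gt <- do.call(rbind, lapply(names(cohort$recordings), function(id) {
    cbind(subject_id = id, cohort$recordings[[id]]$trajectory)
  }))
  utils::write.csv(gt, file.path(dir, "trajectories.csv"), row.names = FALSE)
  invisible(dir)
}
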