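# Calibration-pair construction and the subject-level stratified split.

#' Build calibration-paired samples for one recording
#'
#' Every earlier valid window is paired with every later one: for n valid
#' windows the sample count is n(n-1)/2 and the time span dt between the
#' calibration and estimation windows ranges from one stride upward with no
#' upper restriction. Each sample concatenates the calibration-window
#' features (prefixed `cal.`), the calibration reference BP triplet
#' (`cal.ref_sbp`, `cal.ref_dbp`, `cal.ref_mbp`), the estimation-window
#' features (prefixed `est.`), the demographics (unprefixed), and carries the
#' estimation-window reference as targets `target_sbp` / `target_dbp`.
#' Windows with any missing feature are dropped first.
#'
#' @param features feature table of one recording ([extract_features()]).
#' @return data.frame of calibration samples (0 rows if fewer than 2 windows).
#' @export
build_pairs <- function(features) {
  demo_cols <- intersect(c("age", "weight", "height", "gender"), names(features))
  fcols <- setdiff(feature_columns(features), demo_cols)
  ok <- stats::complete.cases(features[, fcols, drop = FALSE])
  d <- features[ok, , drop = FALSE]
  n <- nrow(d)
  empty <- data.frame()
  if (n < 2L) return(empty)
  if (length(unique(d$subject_id)) != 1L)
    stop("build_pairs: one recording (one subject) at a time")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, "row"]; j <- idx[, "col"]
  Fm <- as.matrix(d[, fcols, drop = FALSE])
  cal <- Fm[i, , drop = FALSE]; colnames(cal) <- paste0("cal.", fcols)
  est <- Fm[j, , drop = FALSE]; colnames(est) <- paste0("est.", fcols)
  out <- data.frame(subject_id = d$subject_id[i],
                    dt = d$start[j] - d$start[i],
                    cal_window = d$window[i], est_window = d$window[j],
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(cal, check.names = FALSE),
               cal.ref_sbp = d$sbp[i], cal.ref_dbp = d$dbp[i],
               cal.ref_mbp = d$mbp[i],
               as.data.frame(est, check.names = FALSE))
  for (dc in demo_cols) out[[dc]] <- d[[dc]][i]
  out$target_sbp <- d$sbp[j]
  out$target_dbp <- d$dbp[j]
  stopifnot(all(out$dt > 0))
  out
}

#' Build calibration-free samples
#'
#' One sample per valid window: the window's features plus demographics, with
#' the window reference BP as targets.
#'
#' @param features feature table ([extract_features()], any number of
#'   subjects).
#' @return data.frame with `est.`-prefixed features, demographics, targets.
#' @export
build_calibration_free <- function(features) {
  if (is.null(features) || nrow(features) == 0L) return(data.frame())
  demo_cols <- intersect(c("age", "weight", "height", "gender"), names(features))
  fcols <- setdiff(feature_columns(features), demo_cols)
  ok <- stats::complete.cases(features[, fcols, drop = FALSE])
  d <- features[ok, , drop = FALSE]
  if (nrow(d) == 0L) return(data.frame())
  Fm <- as.matrix(d[, fcols, drop = FALSE])
  colnames(Fm) <- paste0("est.", fcols)
  out <- data.frame(subject_id = d$subject_id, check.names = FALSE)
  out <- cbind(out, as.data.frame(Fm, check.names = FALSE))
  for (dc in demo_cols) out[[dc]] <- d[[dc]]
  out$target_sbp <- d$sbp
  out$target_dbp <- d$dbp
  out
}

#' Subject-level stratified train/test split
#'
#' Subjects are binned into quartiles of their mean SBP and sampled
#' proportionally within bins so the train and test BP profiles are balanced
#' (per-subject mean SBP difference below half the pooled SD; several seeded
#' draws are attempted and the best-balanced one kept). Each subject lands in
#' exactly one set. Fewer than 5 subjects triggers a plain random split with
#' a warning.
#'
#' @param per_subject_stats data.frame with columns subject_id, sbp_mean,
#'   sbp_sd, dbp_mean, dbp_sd.
#' @param frac training fraction.
#' @param seed integer seed (split is deterministic given it).
#' @return list of class `split_spec`: train, test (subject id vectors), seed.
#' @export
stratified_subject_split <- function(per_subject_stats, frac = 0.8, seed = 1) {
  st <- per_subject_stats
  n <- nrow(st)
  ids <- as.character(st$subject_id)
  n_test <- max(1L, round((1 - frac) * n))
  mk <- function(test_ids) {
    structure(list(train = setdiff(ids, test_ids), test = test_ids, seed = seed),
              class = "split_spec")
  }
  if (n < 5L) {
    warning("stratified_subject_split: too few subjects to stratify; plain random split")
    return(mk(withr::with_seed(seed, sample(ids, n_test))))
  }
  br <- unique(quantile(st$sbp_mean, probs = seq(0, 1, 0.25)))
  bins <- cut(st$sbp_mean, breaks = br, include.lowest = TRUE, labels = FALSE)
  pooled_sd <- sd(st$sbp_mean)
  best <- NULL; best_gap <- Inf
  for (attempt in 1:20) {
    test_ids <- withr::with_seed(derive_seed(seed, attempt), {
      picked <- character(0)
      # proportional draw per bin, then top up at random
      for (b in sort(unique(bins))) {
        in_bin <- ids[bins == b]
        k <- floor(n_test * length(in_bin) / n)
        if (k > 0) picked <- c(picked, sample(in_bin, k))
      }
      pool <- setdiff(ids, picked)
      if (length(picked) < n_test)
        picked <- c(picked, sample(pool, n_test - length(picked)))
      picked[seq_len(n_test)]
    })
    gap <- abs(mean(st$sbp_mean[ids %in% test_ids]) -
                 mean(st$sbp_mean[!ids %in% test_ids]))
    if (gap < best_gap) { best_gap <- gap; best <- test_ids }
    if (gap < 0.5 * pooled_sd) break
  }
  mk(best)
}

#' Per-subject BP summary for stratification
#'
#' @param features feature table for the whole cohort.
#' @return data.frame subject_id, sbp_mean, sbp_sd, dbp_mean, dbp_sd.
#' @export
per_subject_bp_stats <- function(features) {
  agg <- function(v) c(mean = mean(v), sd = sd(v))
  sp <- split(features, features$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(subject_id = d$subject_id[1],
               sbp_mean = mean(d$sbp), sbp_sd = sd(d$sbp),
               dbp_mean = mean(d$dbp), dbp_sd = sd(d$dbp))
  }))
  rownames(out) <- NULL
  out
}
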