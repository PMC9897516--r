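# Pipeline orchestration: synthetic cohort (or CSV input) -> preprocessing ->
# features -> split -> calibration pairs -> selection -> models -> reports.

#' Default run configuration
#'
#' All thresholds at their standard values: 15 / 0.5 Hz 3rd-order Butterworth
#' band-pass, 20-s windows with 50% overlap, SQI gate at 0.75, reference
#' variability gate at 0.10, 80/20 subject-stratified split, 10-fold
#' subject-stratified CV, 100 permutation repetitions, 20% change threshold
#' and 3-min trend bin.
#'
#' @param seed run-level seed; stage seeds are derived from it.
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    synth = list(n_subjects = 40, fs = 125),
    preprocess = list(win = 20, overlap = 0.5, L = 256, sqi_min = 0.75,
                      var_max = 0.10, lp_cut = 15, hp_cut = 0.5, order = 3,
                      max_lag = 2),
    split = list(frac = 0.8),
    select = list(k = 10, nlambda = 100, lambda_min_ratio = 1e-4),
    models = c("lasso", "flat"),
    evaluate = list(rel_threshold = 0.20, bin_edge = 180)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param cfg a configuration list.
#' @return the validated config, invisibly; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  p <- cfg$preprocess
  if (p$sqi_min < 0 || p$sqi_min > 1) stop("config: sqi_min must be in [0, 1]")
  if (p$var_max < 0 || p$var_max > 1) stop("config: var_max must be in [0, 1]")
  if (p$overlap < 0 || p$overlap >= 1) stop("config: overlap must be in [0, 1)")
  if (p$win <= 0) stop("config: win must be positive")
  if (cfg$split$frac <= 0 || cfg$split$frac >= 1) stop("config: split fraction in (0, 1)")
  if (cfg$evaluate$rel_threshold <= 0) stop("config: rel_threshold must be positive")
  bad <- setdiff(cfg$models, c("lasso", "svr", "gpr", "flat"))
  if (length(bad)) stop("config: unknown model kind(s): ", paste(bad, collapse = ","))
  invisible(cfg)
}

pair_feature_cols <- function(df) {
  setdiff(names(df), c("subject_id", "dt", "cal_window", "est_window",
                       "target_sbp", "target_dbp"))
}

# Fit one model kind on a pair table and report train/test error stats.
fit_and_report <- function(kind, target, train, test, fcols, seed,
                           selected = NULL, k = 10) {
  ycol <- paste0("target_", target)
  hyper <- list()
  feats <- fcols
  if (kind == "flat") {
    cal_col <- paste0("cal.ref_", target)
    if (cal_col %in% names(train)) hyper$cal_col <- cal_col
    feats <- character(0)
  } else if (!is.null(selected) && length(selected)) {
    feats <- selected
  }
  spec <- bp_model_spec(kind, target, hyper = hyper, seed = seed)
  m <- fit_bp_model(spec, if (length(feats)) train[, feats, drop = FALSE] else train,
                    train[[ycol]], groups = train$subject_id, k = k)
  list(model = m,
       train = error_stats(predict(m, train), train[[ycol]],
                           train$subject_id, "train"),
       test = error_stats(predict(m, test), test[[ycol]],
                          test$subject_id, "test"))
}

#' Run the full estimation pipeline
#'
#' Generates (or accepts) a cohort, preprocesses every recording, extracts
#' features, performs the subject-stratified split, builds calibration-paired
#' and calibration-free tables, selects features with Lasso on the training
#' pairs, fits the configured models for SBP and DBP, and evaluates absolute
#' accuracy plus the trending ability of the calibration-mode Lasso model
#' (calibration anchored at each test subject's first valid window).
#'
#' @param cfg a `run_config` (see [default_config()]).
#' @param cohort optional pre-built cohort ([synth_cohort()] output); by
#'   default one is generated from `cfg$synth` and `cfg$seed`.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @param keep_tables also return the calibration-pair and calibration-free
#'   sample tables (train/test) for further modelling.
#' @return list with features, split, selections, models, error reports,
#'   trend reports and the config (stamped with a hash).
#' @export
run_pipeline <- function(cfg = default_config(), cohort = NULL, out_dir = NULL,
                         keep_tables = FALSE) {
  validate_config(cfg)
  if (is.null(cohort)) {
    scfg <- do.call(cohort_config, c(cfg$synth, list(seed = cfg$seed)))
    cohort <- synth_cohort(scfg)
  }
  pp <- cfg$preprocess
  features <- do.call(rbind, lapply(names(cohort$recordings), function(id) {
    r <- cohort$recordings[[id]]
    prep <- preprocess_recording(r$ppg, r$abp, win = pp$win,
                                 overlap = pp$overlap, L = pp$L,
                                 sqi_min = pp$sqi_min, var_max = pp$var_max,
                                 lp_cut = pp$lp_cut, hp_cut = pp$hp_cut,
                                 order = pp$order, max_lag = pp$max_lag)
    extract_features(prep, demographics = r$demographics)
  }))
  stats <- per_subject_bp_stats(features)
  split <- stratified_subject_split(stats, frac = cfg$split$frac,
                                    seed = derive_seed(cfg$seed, 11L))
  pairs_all <- do.call(rbind, lapply(split(features, features$subject_id),
                                     build_pairs))
  rownames(pairs_all) <- NULL
  calfree_all <- build_calibration_free(features)
  pt <- function(df, ids) df[df$subject_id %in% ids, , drop = FALSE]
  tabs <- list(
    cal = list(train = pt(pairs_all, split$train), test = pt(pairs_all, split$test)),
    calfree = list(train = pt(calfree_all, split$train),
                   test = pt(calfree_all, split$test))
  )
  out <- list(config = cfg, config_hash = rlang::hash(cfg), split = split,
              features = features, n_pairs = nrow(pairs_all),
              reports = list(), selections = list(), models = list())
  sel_seed <- derive_seed(cfg$seed, 13L)
  for (mode in c("cal", "calfree")) {
    train <- tabs[[mode]]$train; test <- tabs[[mode]]$test
    fcols <- pair_feature_cols(train)
    for (target in c("sbp", "dbp")) {
      y <- train[[paste0("target_", target)]]
      sel <- lasso_select(as.matrix(train[, fcols, drop = FALSE]), y,
                          train$subject_id, k = cfg$select$k,
                          nlambda = cfg$select$nlambda,
                          lambda_min_ratio = cfg$select$lambda_min_ratio,
                          seed = sel_seed)
      out$selections[[mode]][[target]] <- sel
      for (kind in cfg$models) {
        if (kind == "flat" && mode == "calfree" &&
            !paste0("cal.ref_", target) %in% names(train)) {
          # calibration-free flat model: training-set mean
        }
        fr <- fit_and_report(kind, target, train, test, fcols,
                             seed = derive_seed(cfg$seed, 17L),
                             selected = sel$selected_features,
                             k = cfg$select$k)
        out$models[[mode]][[target]][[kind]] <- fr$model
        out$reports[[mode]][[target]][[kind]] <-
          list(train = fr$train, test = fr$test)
      }
    }
  }
  # trending ability of the calibration-mode Lasso model on the test set
  if ("lasso" %in% cfg$models) {
    out$trend <- pipeline_trending(out, tabs$cal$test, cfg)
  }
  if (keep_tables) out$tables <- tabs
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

# Per test subject, anchor the calibration at the first valid window and
# predict every later window; extract >= 20% changes and compute trending
# statistics per time-span bin.
pipeline_trending <- function(out, test_pairs, cfg) {
  trends <- list()
  for (target in c("sbp", "dbp")) {
    m <- out$models$cal[[target]]$lasso
    series <- list()
    for (sid in unique(test_pairs$subject_id)) {
      d <- test_pairs[test_pairs$subject_id == sid, , drop = FALSE]
      first_w <- min(d$cal_window)
      d <- d[d$cal_window == first_w, , drop = FALSE]
      if (nrow(d) < 2) next
      d <- d[order(d$dt), ]
      ref0 <- d[[paste0("cal.ref_", target)]][1]
      series[[sid]] <- data.frame(
        subject_id = sid,
        t = c(0, d$dt),
        ref = c(ref0, d[[paste0("target_", target)]]),
        est = c(ref0, predict(m, d)))
    }
    if (!length(series)) next
    s <- do.call(rbind, series)
    pairs <- extract_changes(s$ref, s$est, s$t, s$subject_id,
                             rel_threshold = cfg$evaluate$rel_threshold,
                             bin_edge = cfg$evaluate$bin_edge)
    trends[[target]] <- lapply(split(pairs, pairs$timespan_bin), function(b) {
      if (nrow(b) < 2) return(NULL)
      c(four_quadrant(b), polar = list(polar_stats(b)))
    })
    trends[[target]]$pairs <- pairs
  }
  trends
}

write_run_artifacts <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(train = out$split$train, test = out$split$test,
                            seed = out$split$seed),
                       file.path(out_dir, "split.json"), auto_unbox = TRUE)
  summarize <- function(r) list(me = r$me, stde = r$stde, n = r$n)
  rep_json <- lapply(out$reports, function(mode)
    lapply(mode, function(tg) lapply(tg, function(kind)
      lapply(kind, summarize))))
  jsonlite::write_json(list(config_hash = out$config_hash,
                            seed = out$config$seed,
                            n_pairs = out$n_pairs, reports = rep_json),
                       file.path(out_dir, "reports.json"), auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(unclass(out$config), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
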