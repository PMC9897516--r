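# Evaluation: absolute accuracy (ME/STDE, subject-wise) and trending ability
# (four-quadrant and polar-plot statistics on >= 20% BP changes).

#' Mean error and error standard deviation
#'
#' error = estimate - reference; ME is its mean and STDE its sample standard
#' deviation, reported overall and per subject.
#'
#' @param est,ref aligned numeric vectors, mmHg.
#' @param subjects subject id per element.
#' @param split label ("train"/"test") carried in the report.
#' @return list of class `error_report`: me, stde, n, per_subject, split.
#' @export
error_stats <- function(est, ref, subjects = rep("all", length(est)),
                        split = "test") {
  stopifnot(length(est) == length(ref))
  if (length(est) <= 1L) stop("error_stats: need n > 1")
  err <- est - ref
  per <- do.call(rbind, lapply(split(err, subjects), function(e) {
    data.frame(me = mean(e), stde = if (length(e) > 1) sd(e) else NA_real_,
               n = length(e))
  }))
  per$subject_id <- rownames(per); rownames(per) <- NULL
  structure(list(me = mean(err), stde = sd(err), n = length(err),
                 per_subject = per[, c("subject_id", "me", "stde", "n")],
                 split = split),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %s: ME = %.2f, STDE = %.2f mmHg (n = %d)\n",
              x$split, x$me, x$stde, x$n))
  invisible(x)
}

#' Extract significant BP changes for trending analysis
#'
#' Every ordered window pair (i < j) of a subject's reference series defines
#' a change d_inv = ref_j - ref_i; it is retained iff |d_inv| / ref_i is at
#' least `rel_threshold` (changes of exactly 20% are included). The matching
#' estimated change d_est is read from the estimate series at the same
#' windows, and each pair is binned by its time span at `bin_edge`.
#'
#' @param series_ref,series_est reference / estimated BP per window, mmHg.
#' @param t window start times in seconds.
#' @param subject_id subject identifier (scalar) or vector per window.
#' @param rel_threshold relative change threshold (0.20 = 20%).
#' @param bin_edge time-span bin edge in seconds (3 min).
#' @return data.frame of trend pairs: subject_id, d_inv, d_est, dt,
#'   timespan_bin ("<=3min" / ">3min").
#' @export
extract_changes <- function(series_ref, series_est, t = seq_along(series_ref),
                            subject_id = "s1", rel_threshold = 0.20,
                            bin_edge = 180) {
  n <- length(series_ref)
  stopifnot(length(series_est) == n, length(t) == n)
  if (length(subject_id) == 1L) subject_id <- rep(subject_id, n)
  out <- list()
  for (sid in unique(subject_id)) {
    w <- which(subject_id == sid)
    if (length(w) < 2L) next
    idx <- which(upper.tri(matrix(0, length(w), length(w))), arr.ind = TRUE)
    i <- w[idx[, "row"]]; j <- w[idx[, "col"]]
    bad <- series_ref[i] <= 0
    if (any(bad)) {
      warning("extract_changes: skipping ", sum(bad),
              " pair(s) with non-positive baseline reference")
      i <- i[!bad]; j <- j[!bad]
    }
    d_inv <- series_ref[j] - series_ref[i]
    keep <- abs(d_inv) / series_ref[i] >= rel_threshold
    if (!any(keep)) next
    out[[sid]] <- data.frame(subject_id = sid,
                             d_inv = d_inv[keep],
                             d_est = series_est[j][keep] - series_est[i][keep],
                             dt = t[j][keep] - t[i][keep])
  }
  if (!length(out))
    return(data.frame(subject_id = character(0), d_inv = numeric(0),
                      d_est = numeric(0), dt = numeric(0),
                      timespan_bin = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$timespan_bin <- ifelse(res$dt <= bin_edge, "<=3min", ">3min")
  res
}

#' Four-quadrant concordance
#'
#' Concordance rate: percentage of change pairs whose reference and estimated
#' changes share a sign (a zero estimated change counts as discordant unless
#' the reference change is also zero), plus the Pearson correlation of the
#' two change series.
#'
#' @param pairs data.frame with columns d_inv, d_est ([extract_changes()]).
#' @return list: cr (percent), pearson_r, n.
#' @export
four_quadrant <- function(pairs) {
  if (nrow(pairs) < 2L) stop("four_quadrant: need >= 2 pairs")
  conc <- sign(pairs$d_inv) == sign(pairs$d_est)
  list(cr = 100 * mean(conc),
       pearson_r = cor(pairs$d_inv, pairs$d_est),
       n = nrow(pairs))
}

#' Polar-plot trending statistics
#'
#' Each pair is mapped to a polar point: radius = (d_inv + d_est) / 2 (mean
#' amplitude of change) and angle = deviation of atan2(d_est, d_inv) from the
#' 45-degree identity line, wrapped to (-180, 180]. Pairs with negative mean
#' change are mirrored through the origin first so angles compare
#' like-direction changes; zero-magnitude pairs are excluded. Reported are
#' the angular concordance rate within +/- `limit` degrees, the angular bias
#' (mean angle), angular SD, and 95% radial limits of agreement
#' (bias +/- 1.96 SD).
#'
#' @param pairs data.frame with columns d_inv, d_est.
#' @param limit angular limit in degrees.
#' @return list of class `trend_report`: angular_cr, angular_bias,
#'   angular_sd, radial_loa_95, radius, theta, n.
#' @export
polar_stats <- function(pairs, limit = 30) {
  d_inv <- pairs$d_inv; d_est <- pairs$d_est
  nz <- !(d_inv == 0 & d_est == 0)
  d_inv <- d_inv[nz]; d_est <- d_est[nz]
  if (length(d_inv) < 2L) stop("polar_stats: need >= 2 nonzero pairs")
  radius <- (d_inv + d_est) / 2
  refl <- radius < 0
  d_inv[refl] <- -d_inv[refl]; d_est[refl] <- -d_est[refl]
  radius <- abs(radius)
  theta <- atan2(d_est, d_inv) * 180 / pi - 45
  theta <- ((theta + 180) %% 360) - 180
  theta[theta == -180] <- 180
  bias <- mean(theta); s <- sd(theta)
  structure(list(angular_cr = 100 * mean(abs(theta) <= limit),
                 angular_bias = bias, angular_sd = s,
                 radial_loa_95 = c(low = bias - 1.96 * s,
                                   high = bias + 1.96 * s),
                 radius = radius, theta = theta, n = length(theta)),
            class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf(paste0("<trend_report> n = %d: angular CR(30) = %.2f%%, ",
                     "bias = %.2f deg, SD = %.2f deg, 95%% LoA [%.2f, %.2f]\n"),
              x$n, x$angular_cr, x$angular_bias, x$angular_sd,
              x$radial_loa_95["low"], x$radial_loa_95["high"]))
  invisible(x)
}

#' Four-quadrant scatter plot
#'
#' @param pairs trend pairs ([extract_changes()]).
#' @param path optional output file.
#' @return ggplot object.
#' @export
plot_four_quadrant <- function(pairs, path = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$d_inv, y = .data$d_est)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "Reference change (mmHg)", y = "Estimated change (mmHg)") +
    ggplot2::theme_minimal()
  if (!is.null(path)) { ggplot2::ggsave(path, p, width = 5, height = 5); return(invisible(p)) }
  p
}

#' Polar trending plot
#'
#' Shows the change pairs in (radius, angle) coordinates with the +/-30
#' degree radial limits (solid), the angular bias (dash-dotted) and the 95%
#' limits of agreement (dashed).
#'
#' @param trend a `trend_report` from [polar_stats()].
#' @param limit radial limit in degrees.
#' @param path optional output file.
#' @return ggplot object.
#' @export
plot_polar <- function(trend, limit = 30, path = NULL) {
  d <- data.frame(radius = trend$radius, theta = trend$theta)
  guides <- data.frame(theta = c(-limit, limit, trend$angular_bias,
                                 trend$radial_loa_95),
                       style = c("limit", "limit", "bias", "loa", "loa"))
  rmax <- max(d$radius)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$radius)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_vline(data = guides,
                        ggplot2::aes(xintercept = .data$theta,
                                     linetype = .data$style)) +
    ggplot2::scale_linetype_manual(values = c(limit = "solid", bias = "dotdash",
                                              loa = "dashed"), guide = "none") +
    ggplot2::coord_polar(theta = "x", start = pi / 2, direction = -1) +
    ggplot2::xlim(-180, 180) + ggplot2::ylim(0, rmax) +
    ggplot2::labs(x = "Angle from identity line (deg)",
                  y = "Mean change amplitude (mmHg)") +
    ggplot2::theme_minimal()
  if (!is.null(path)) { ggplot2::ggsave(path, p, width = 5.5, height = 5.5); return(invisible(p)) }
  p
}
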