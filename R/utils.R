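# Internal helpers shared across modules.

#' @importFrom stats approx cor median quantile rnorm runif rbinom sd
#' @importFrom stats coef optim predict setNames weighted.mean dist
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Local extrema of a numeric vector.
#'
#' Plateau-safe: runs of equal values are collapsed before sign-change
#' detection and the first index of the run is reported. Endpoints are never
#' extrema.
#'
#' @param x numeric vector.
#' @return data.frame with columns `idx` (integer) and `type` ("max"/"min"),
#'   ordered by index.
#' @noRd
local_extrema <- function(x) {
  n <- length(x)
  empty <- data.frame(idx = integer(0), type = character(0))
  if (n < 3L) return(empty)
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(empty)
  first_idx <- cumsum(c(1L, r$lengths[-k]))
  d <- sign(diff(r$values))
  # interior run i is a max if slope flips + -> -, min if - -> +
  types <- character(0); idxs <- integer(0)
  for (i in 2:(k - 1L)) {
    if (d[i - 1L] > 0 && d[i] < 0) { idxs <- c(idxs, first_idx[i]); types <- c(types, "max") }
    if (d[i - 1L] < 0 && d[i] > 0) { idxs <- c(idxs, first_idx[i]); types <- c(types, "min") }
  }
  data.frame(idx = idxs, type = types)
}

#' Drop low-prominence ripple extrema.
#'
#' Adjacent max/min pairs whose amplitude gap is below `min_prom` are removed
#' together, which preserves the max/min alternation of the sequence.
#'
#' @noRd
prune_extrema <- function(ex, x, min_prom) {
  idx <- ex$idx; type <- ex$type
  while (length(idx) >= 2L) {
    gaps <- abs(diff(x[idx]))
    m <- which.min(gaps)
    if (gaps[m] >= min_prom) break
    idx <- idx[-c(m, m + 1L)]; type <- type[-c(m, m + 1L)]
  }
  data.frame(idx = idx, type = type)
}

#' Resample a vector to a fixed length by linear interpolation
#' @noRd
resample_to <- function(x, L) {
  if (length(x) == L) return(as.numeric(x))
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = L))$y
}

# Correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Assign subjects to cross-validation folds.
#'
#' Every sample of a subject lands in exactly one fold, so no subject spans
#' fold-train and fold-validation sets.
#'
#' @param groups subject identifier per sample.
#' @param k number of folds.
#' @param seed integer seed for the subject shuffle.
#' @return integer fold id per sample.
#' @export
subject_folds <- function(groups, k = 10, seed = 1) {
  subs <- unique(groups)
  k <- min(k, length(subs))
  # shuffle subjects, deal round-robin
  shuffled <- subs[withr::with_seed(seed, sample(seq_along(subs)))]
  fold_of <- setNames(rep_len(seq_len(k), length(subs)), shuffled)
  as.integer(fold_of[as.character(groups)])
}

# Derive a child seed from a run seed; stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}
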