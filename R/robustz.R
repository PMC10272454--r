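# Robust median/MAD normalisation of time-frequency power, trial-level
# outlier removal, and band x window averaging.

#' Frequency bands of interest
#'
#' Theta 4-7 Hz, alpha 8-12 Hz, beta 16-24 Hz (inclusive integer bins).
#' @return named list of `c(lo, hi)` in Hz.
#' @export
standard_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(16, 24))
}

#' Analysis windows relative to the texture transition
#'
#' Active pre-transition baseline -650..-200 ms and transition 0..450 ms,
#' half-open on the 0.01 s time-bin grid (45 bins each).
#' @param pre pre-transition window `c(t0, t1)` (s).
#' @return named list of `c(t0, t1)` in seconds.
#' @export
standard_windows <- function(pre = c(-0.65, -0.20)) {
  list(pre = pre, transition = c(0, 0.45))
}

#' Robust z-scoring of time-frequency power
#'
#' Converts power to `z = (P - median) / MAD`, with the unscaled MAD (no
#' normal-consistency factor), per participant and per (channel, frequency).
#' The pooling of the reference distribution is controlled by `pool`:
#'
#' * `"epoch"` (default): median and MAD are taken over all trials (both
#'   conditions pooled) and all epoch time bins. The z at each time bin then
#'   measures deviation from the trial-and-epoch-typical power at that
#'   channel and frequency, so event-locked power changes common to all
#'   trials (the quantity of interest) survive normalisation.
#' * `"per_bin"`: median and MAD over trials separately at each time bin.
#'   This enforces median 0 / MAD 1 across trials at every bin, but thereby
#'   also removes any component common to all trials at a bin — including a
#'   perfectly time-locked power change — leaving only trial-to-trial
#'   deviations.
#'
#' Cells with `MAD = 0` are flagged `NA` and excluded downstream.
#'
#' @param tf a raw [welch_tf()] `tf_series`.
#' @param pool reference-distribution pooling (see above).
#' @return the `tf_series` with `$power` replaced by z values,
#'   `$normalisation = "robust_z"`, and `$center`/`$scale` holding the
#'   median and MAD used.
#' @export
robust_z <- function(tf, pool = c("epoch", "per_bin")) {
  pool <- match.arg(pool)
  d <- dim(tf$power)
  n_tr <- d[1]
  if (n_tr < 2) stop_tex("need at least 2 trials to normalise", "parameter_error")
  if (pool == "per_bin") {
    m <- matrix(tf$power, n_tr, prod(d[-1]))
    med <- col_medians(m)
    mad_ <- col_medians(abs(m - rep(med, each = n_tr)))
    z <- (m - rep(med, each = n_tr)) / rep(mad_, each = n_tr)
    z[, mad_ == 0] <- NA_real_
    tf$power <- array(z, d)
    tf$center <- array(med, d[-1])
    tf$scale <- array(mad_, d[-1])
  } else {
    # pool trials and time bins: reorder to (trial, time) x (channel, freq)
    a <- aperm(tf$power, c(1, 4, 2, 3))
    m <- matrix(a, n_tr * d[4], d[2] * d[3])
    med <- col_medians(m)
    mad_ <- col_medians(abs(m - rep(med, each = nrow(m))))
    z <- (m - rep(med, each = nrow(m))) / rep(mad_, each = nrow(m))
    z[, mad_ == 0] <- NA_real_
    tf$power <- aperm(array(z, c(n_tr, d[4], d[2], d[3])), c(1, 3, 4, 2))
    tf$center <- array(med, d[2:3])
    tf$scale <- array(mad_, d[2:3])
  }
  tf$normalisation <- "robust_z"
  tf$pool <- pool
  tf
}

#' Remove trial-level outliers
#'
#' Drops values whose magnitude exceeds `threshold` (z values are already in
#' MAD units, so the default implements a 5-MAD rule). A value of exactly
#' `threshold` is retained.
#'
#' @param x numeric vector of trial-level z values.
#' @param threshold exclusion threshold (MAD units).
#' @return the retained values; warns and returns an empty vector when all
#'   trials are excluded.
#' @export
remove_outliers <- function(x, threshold = 5) {
  x <- x[!is.na(x)]
  keep <- abs(x) <= threshold
  if (length(x) > 0 && !any(keep))
    warning("all trials excluded by the outlier rule")
  x[keep]
}

#' Trial-level band x window averages of z-scored power
#'
#' For each trial, channel, frequency band and analysis window, the mean z
#' over the band's (inclusive) frequency bins and the window's half-open
#' time bins.
#'
#' @param tf a z-normalised `tf_series` (see [robust_z()]).
#' @param bands named list of `c(lo, hi)` Hz (default [standard_bands()]).
#' @param windows named list of `c(t0, t1)` s (default [standard_windows()]).
#' @return data.frame with columns `participant`, `trial`, `channel`,
#'   `condition`, `band`, `window`, `value`.
#' @export
band_window_average <- function(tf, bands = standard_bands(),
                                windows = standard_windows()) {
  if (!identical(tf$normalisation, "robust_z"))
    stop_tex("band_window_average expects a z-normalised tf_series",
             "parameter_error")
  d <- dim(tf$power)
  n_tr <- d[1]; n_ch <- d[2]
  out <- list()
  for (bn in names(bands)) {
    fsel <- which(tf$freqs >= bands[[bn]][1] & tf$freqs <= bands[[bn]][2])
    if (length(fsel) == 0)
      stop_tex(sprintf("band %s outside computed frequencies", bn),
               "parameter_error")
    for (wn in names(windows)) {
      tsel <- which(tf$times >= windows[[wn]][1] - 1e-9 &
                      tf$times < windows[[wn]][2] - 1e-9)
      if (length(tsel) == 0) stop_tex(sprintf("window %s empty", wn),
                                      "parameter_error")
      cell <- tf$power[, , fsel, tsel, drop = FALSE]
      val <- apply(cell, c(1, 2), mean, na.rm = TRUE)
      val[is.nan(val)] <- NA_real_
      out[[paste(bn, wn)]] <- data.frame(
        participant = tf$participant,
        trial = rep(seq_len(n_tr), n_ch),
        channel = rep(tf$channels, each = n_tr),
        condition = rep(tf$condition, n_ch),
        band = bn, window = wn,
        value = as.vector(val),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate trial-level band/window values to participant means
#'
#' Applies the trial-level outlier rule within each aggregation cell, then
#' averages the surviving trials.
#'
#' @param bw trial-level table from [band_window_average()].
#' @param by grouping columns in addition to
#'   `participant`/`channel`/`band`/`window`; use `"condition"` to keep the
#'   two transition directions apart, or `character(0)` to pool them.
#' @param threshold outlier threshold passed to [remove_outliers()].
#' @return data.frame of cell means (`value`) with trial counts (`n`).
#' @export
aggregate_band_windows <- function(bw, by = character(0), threshold = 5) {
  keys <- c("participant", "channel", "band", "window", by)
  grp <- interaction(bw[keys], drop = TRUE, lex.order = TRUE)
  vals <- split(bw$value, grp)
  means <- vapply(vals, function(v) {
    v <- suppressWarnings(remove_outliers(v, threshold))
    if (length(v) == 0) NA_real_ else mean(v)
  }, 1)
  ns <- vapply(vals, function(v)
    length(suppressWarnings(remove_outliers(v, threshold))), 1L)
  meta <- bw[match(names(vals), as.character(grp)), keys, drop = FALSE]
  res <- cbind(meta, value = means, n = ns)
  rownames(res) <- NULL
  res
}
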