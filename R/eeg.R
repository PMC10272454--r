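# EEG containers, preprocessing, and transition-locked epoching.

# Squared magnitude response |H|^2 of a digital filter on the length-n FFT
# grid: the transfer function of forward-backward (zero-phase) filtering.
butter_gain2 <- function(flt, n) {
  w <- 2 * pi * (0:(n - 1L)) / n
  z <- exp(-1i * w)
  H <- as.vector(outer(z, seq_along(flt$b) - 1L, `^`) %*% flt$b) /
    as.vector(outer(z, seq_along(flt$a) - 1L, `^`) %*% flt$a)
  Mod(H)^2
}

#' Continuous multichannel EEG recording
#'
#' @param signals numeric matrix, samples x channels (microvolts).
#' @param sample_rate sampling rate (Hz).
#' @param layout layout data.frame ([layout_geodesic_129()]); one row per
#'   channel, order matching the columns of `signals`.
#' @param reference reference label (default `"Cz"`).
#' @param events optional event table carried with the recording (e.g.
#'   trial onsets in seconds).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, sample_rate, layout = layout_geodesic_129(),
                          reference = "Cz", events = NULL) {
  stopifnot(is.matrix(signals))
  if (ncol(signals) != nrow(layout))
    stop_tex("signals/layout channel mismatch", "parameter_error")
  colnames(signals) <- layout$label
  structure(list(signals = signals, sample_rate = sample_rate,
                 layout = layout, reference = reference, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz (ref %s)\n",
              ncol(x$signals), nrow(x$signals), x$sample_rate, x$reference))
  invisible(x)
}

#' Standard EEG preprocessing
#'
#' Zero-phase 4th-order Butterworth band-pass (`hp`-`lp` Hz) and band-stop
#' notch around the mains frequency, resampling to `target_rate`, and
#' common-average re-referencing (the channel mean is subtracted at every
#' sample). The zero-phase filtering (forward-backward application, i.e.
#' the squared magnitude response of the named Butterworth designs with no
#' phase distortion) is applied in the frequency domain in one pass over
#' all channels; the recording's resting lead-in/lead-out absorbs the
#' circular edge effects. Resampling uses linear interpolation, which is
#' transparent here because the low-pass corner sits well below the new
#' Nyquist rate.
#'
#' @param rec an [eeg_recording()].
#' @param hp,lp band-pass corners (Hz).
#' @param notch band-stop interval (Hz), `NULL` to skip.
#' @param target_rate output rate (Hz).
#' @return the preprocessed [eeg_recording()] at `target_rate`, reference
#'   `"common-average"`.
#' @export
preprocess <- function(rec, hp = 0.5, lp = 100, notch = c(48, 52),
                       target_rate = 256) {
  fs <- rec$sample_rate
  if (fs < target_rate)
    stop_tex("sample rate below target rate", "rate_error")
  nyq <- fs / 2
  n <- nrow(rec$signals)
  gain <- butter_gain2(signal::butter(4, c(hp, lp) / nyq, type = "pass"),
                       n)
  if (!is.null(notch))
    gain <- gain * butter_gain2(signal::butter(4, notch / nyq,
                                               type = "stop"), n)
  x <- rec$signals
  for (j in seq_len(ncol(x)))
    x[, j] <- Re(stats::fft(stats::fft(x[, j]) * gain,
                            inverse = TRUE)) / n
  if (target_rate != fs) {
    t_old <- (seq_len(nrow(x)) - 1L) / fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate)
    xn <- matrix(0, length(t_new), ncol(x))
    for (j in seq_len(ncol(x)))
      xn[, j] <- stats::approx(t_old, x[, j], t_new)$y
    x <- xn
  }
  x <- x - rowMeans(x)
  eeg_recording(x, target_rate, rec$layout, reference = "common-average",
                events = rec$events)
}

#' Set of transition-locked EEG epochs
#'
#' @param data numeric array, trial x channel x time (microvolts).
#' @param condition per-trial labels (`"smooth_to_rough"`/`"rough_to_smooth"`).
#' @param sample_rate epoch sampling rate (Hz).
#' @param tmin epoch start relative to the transition (s).
#' @param channels channel labels.
#' @param participant optional participant id.
#' @return an object of class `epoch_set`; `$times` holds the half-open
#'   sample grid `tmin + (0:(n-1))/sample_rate`.
#' @export
epoch_set <- function(data, condition, sample_rate, tmin = -2,
                      channels = NULL, participant = NA_character_) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(condition))
  structure(list(
    data = data, condition = condition, sample_rate = sample_rate,
    tmin = tmin,
    times = tmin + (seq_len(dim(data)[3]) - 1L) / sample_rate,
    channels = channels %||% sprintf("E%d", seq_len(dim(data)[2])),
    participant = participant), class = "epoch_set")
}

#' Epoch a recording around texture-transition events
#'
#' Cuts a window of `tmin`..`tmax` seconds (half-open, so a 4 s window at
#' 256 Hz is exactly 1024 samples) around each event's `t_cross`. Events too
#' close to the recording edge are skipped with a warning.
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param events data.frame with columns `t_cross` (s) and `direction`.
#' @param tmin,tmax window bounds relative to the transition (s).
#' @param participant optional participant id stored on the result.
#' @return an [epoch_set()].
#' @export
epoch_eeg <- function(rec, events, tmin = -2, tmax = 2,
                      participant = NA_character_) {
  fs <- rec$sample_rate
  n_time <- as.integer(round((tmax - tmin) * fs))
  n_samp <- nrow(rec$signals)
  starts <- as.integer(round((events$t_cross + tmin) * fs)) + 1L
  ok <- starts >= 1L & starts + n_time - 1L <= n_samp
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge; skipped",
                    sum(!ok)))
  keep <- which(ok)
  dat <- array(0, c(length(keep), ncol(rec$signals), n_time))
  for (i in seq_along(keep)) {
    s <- starts[keep[i]]
    dat[i, , ] <- t(rec$signals[s:(s + n_time - 1L), , drop = FALSE])
  }
  epoch_set(dat, events$direction[keep], fs, tmin = tmin,
            channels = colnames(rec$signals), participant = participant)
}
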