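# Sliding-window Welch time-frequency transform.
#
# Power at each of 400 time bins (0.01 s pitch over the half-open epoch
# [-2, 2) s) is the one-sided Hanning-tapered periodogram of the 1 s window
# centred on the bin. Windows are truncated at the epoch edges; the taper
# normalisation then uses the truncated taper's energy, which keeps the
# estimate unbiased in expected power right up to the edges. A 1 s window
# at 256 Hz gives exactly 1 Hz frequency resolution, so the default is a
# single full-length segment per window; sub-segment averaging (classic
# Welch) is available but trades away the 1 Hz resolution.

#' Time-frequency power of an epoch set
#'
#' @param epochs an [epoch_set()] (4 s at 256 Hz in the standard analysis).
#' @param window_len analysis window length (s).
#' @param hop time-bin pitch (s); bin centres sit on the half-open grid
#'   `tmin + hop * (0:(n_bins-1))`.
#' @param freqs frequencies to keep (Hz); must be multiples of the window's
#'   resolution `1/window_len`.
#' @param n_segments sub-segments per window (50% overlap, periodograms
#'   averaged). The default 1 uses the whole window.
#' @return an object of class `tf_series`: `$power` is a trial x channel x
#'   frequency x time-bin array; `$freqs`, `$times`, `$condition`,
#'   `$channels` label the dimensions; `$normalisation` is `"raw"`.
#' @export
welch_tf <- function(epochs, window_len = 1, hop = 0.01, freqs = 1:80,
                     n_segments = 1L) {
  fs <- epochs$sample_rate
  n_time <- dim(epochs$data)[3]
  tmin <- epochs$tmin
  epoch_len <- n_time / fs
  win_n <- as.integer(round(window_len * fs))
  if (win_n > n_time)
    stop_tex("epoch shorter than the analysis window", "length_error")
  n_bins <- as.integer(round(epoch_len / hop))
  centers <- tmin + hop * (seq_len(n_bins) - 1L)
  t_samp <- epochs$times

  if (n_segments > 1L) {
    return(welch_tf_segmented(epochs, window_len, hop, freqs, n_segments))
  }

  # per-bin contiguous sample windows, taper and scaling, precomputed once
  j1 <- pmax(1L, as.integer(ceiling((centers - window_len / 2 - tmin) * fs -
                                      1e-9)) + 1L)
  j2 <- pmin(n_time, as.integer(ceiling((centers + window_len / 2 - tmin) *
                                          fs - 1e-9)))
  idx <- matrix(n_time + 1L, win_n, n_bins)   # points at the zero pad
  tap <- matrix(0, win_n, n_bins)
  for (b in seq_len(n_bins)) {
    jj <- j1[b]:j2[b]
    k <- (t_samp[jj] - (centers[b] - window_len / 2)) * fs
    w <- 0.5 * (1 - cos(2 * pi * k / (win_n - 1)))
    m <- length(jj)
    idx[seq_len(m), b] <- jj
    tap[seq_len(m), b] <- w
  }
  sumw2 <- colSums(tap^2)
  scale <- 2 / (fs * sumw2)

  fres <- 1 / window_len
  fidx <- as.integer(round(freqs / fres)) + 1L
  if (any(abs(freqs / fres - round(freqs / fres)) > 1e-9) ||
      any(fidx < 1L | fidx > win_n))
    stop_tex("freqs must be multiples of 1/window_len within the band",
             "parameter_error")

  n_tr <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  n_f <- length(fidx)
  power <- array(0, c(n_tr, n_ch, n_f, n_bins))
  # channels are batched into one windowing + transform per chunk per
  # trial; for small frequency sets a direct DFT as two real matrix
  # products (BLAS) beats a full FFT of every window
  use_dft <- n_f <= win_n %/% 4L
  if (use_dft) {
    ph <- outer(2 * pi * (fidx - 1L) / win_n, 0:(win_n - 1L))
    FR <- cos(ph); FI <- -sin(ph)
  }
  chunk <- min(n_ch, 24L)
  idxc_cache <- list()
  scl <- rep(scale, each = n_f)
  for (tr in seq_len(n_tr)) {
    for (c0 in seq(1L, n_ch, by = chunk)) {
      cs <- c0:min(n_ch, c0 + chunk - 1L)
      nc <- length(cs)
      key <- as.character(nc)
      if (is.null(idxc_cache[[key]])) {
        off <- rep((seq_len(nc) - 1L) * (n_time + 1L),
                   each = win_n * n_bins)
        idxc_cache[[key]] <- list(
          idx = rep.int(as.vector(idx), nc) + off,
          tap = matrix(rep.int(as.vector(tap), nc), win_n, n_bins * nc))
      }
      cc <- idxc_cache[[key]]
      xp <- rbind(t(matrix(epochs$data[tr, cs, , drop = FALSE],
                           nc, n_time)), 0)
      X <- matrix(xp[cc$idx], win_n, n_bins * nc) * cc$tap
      P <- if (use_dft) {
        (FR %*% X)^2 + (FI %*% X)^2
      } else {
        S <- stats::mvfft(X)
        Mod(S[fidx, , drop = FALSE])^2
      }
      dim(P) <- c(n_f, n_bins, nc)
      for (k in seq_len(nc))
        power[tr, cs[k], , ] <- P[, , k] * scl
    }
  }
  structure(list(power = power, freqs = freqs, times = centers,
                 condition = epochs$condition, channels = epochs$channels,
                 participant = epochs$participant,
                 sample_rate = fs, window_len = window_len, hop = hop,
                 normalisation = "raw"),
            class = "tf_series")
}

# Classic Welch variant: each window split into n_segments sub-segments at
# 50% overlap, each Hanning-tapered; periodograms averaged and mapped onto
# the requested frequencies by nearest bin. Coarser frequency resolution.
welch_tf_segmented <- function(epochs, window_len, hop, freqs, n_segments) {
  fs <- epochs$sample_rate
  n_time <- dim(epochs$data)[3]
  tmin <- epochs$tmin
  win_n <- as.integer(round(window_len * fs))
  seg_n <- as.integer(floor(win_n / ((n_segments + 1) / 2)))
  step <- as.integer(floor(seg_n / 2))
  n_bins <- as.integer(round(n_time / fs / hop))
  centers <- tmin + hop * (seq_len(n_bins) - 1L)
  w <- hann_taper(seg_n)
  sumw2 <- sum(w^2)
  fgrid <- (0:(seg_n - 1L)) * fs / seg_n
  fidx <- vapply(freqs, function(f) which.min(abs(fgrid - f)), 1L)
  n_tr <- dim(epochs$data)[1]; n_ch <- dim(epochs$data)[2]
  power <- array(0, c(n_tr, n_ch, length(freqs), n_bins))
  for (b in seq_len(n_bins)) {
    s0 <- as.integer(round((centers[b] - window_len / 2 - tmin) * fs)) + 1L
    starts <- s0 + step * (seq_len(n_segments) - 1L)
    starts <- starts[starts >= 1L & starts + seg_n - 1L <= n_time]
    if (length(starts) == 0L) starts <- max(1L, min(s0, n_time - seg_n + 1L))
    for (tr in seq_len(n_tr)) for (ch in seq_len(n_ch)) {
      acc <- numeric(length(freqs))
      for (s in starts) {
        X <- stats::fft(epochs$data[tr, ch, s:(s + seg_n - 1L)] * w)
        acc <- acc + 2 * Mod(X[fidx])^2 / (fs * sumw2)
      }
      power[tr, ch, , b] <- acc / length(starts)
    }
  }
  structure(list(power = power, freqs = freqs, times = centers,
                 condition = epochs$condition, channels = epochs$channels,
                 participant = epochs$participant,
                 sample_rate = fs, window_len = window_len, hop = hop,
                 normalisation = "raw"),
            class = "tf_series")
}

#' @export
print.tf_series <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("tf_series (%s): %d trials x %d channels x %d freqs x %d bins\n",
              x$normalisation, d[1], d[2], d[3], d[4]))
  invisible(x)
}
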