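# Preprocessing, epoching, and the sliding Welch time-frequency transform.

# Sinusoid test recording; channels alternate sign so the common-average
# re-reference is a no-op and the filters themselves are what is tested.
make_rec <- function(f, n_ch = 4, fs = 1000, dur = 10, amp = 10) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  base <- amp * sin(2 * pi * f * t)
  sig <- sapply(seq_len(n_ch), function(j)
    base * (-1)^(j + 1) + rnorm(length(t), 0, 0.01))
  lay <- layout_geodesic_129()[seq_len(n_ch), ]
  eeg_recording(sig, fs, lay)
}

test_that("preprocessing notches mains, kills DC, and re-references", {
  set.seed(2)
  r50 <- make_rec(50)
  out <- preprocess(r50)
  mid <- (nrow(out$signals) %/% 4):(3 * nrow(out$signals) %/% 4)
  # residual 50 Hz amplitude under 5% of input
  expect_lt(stats::sd(out$signals[mid, 1]), 0.05 * 10 / sqrt(2))
  # in-band content passes essentially unchanged
  r10 <- make_rec(10)
  out10 <- preprocess(r10)
  expect_gt(stats::sd(out10$signals[mid, 1]), 0.9 * 10 / sqrt(2))
  # DC offset is removed by the high-pass
  lay <- layout_geodesic_129()[1:3, ]
  dc <- eeg_recording(matrix(7, 5000, 3), 1000, lay)
  outdc <- preprocess(dc)
  expect_lt(max(abs(outdc$signals)), 0.2)
  # common-average property: channel mean is zero at every sample
  set.seed(3)
  rnd <- eeg_recording(matrix(rnorm(5000 * 3), 5000, 3), 1000, lay)
  outr <- preprocess(rnd)
  expect_lt(max(abs(rowMeans(outr$signals))), 1e-10)
  expect_equal(outr$sample_rate, 256)
  expect_error(preprocess(eeg_recording(matrix(0, 100, 3), 100, lay)),
               class = "rate_error")
})

test_that("epoching aligns the transition to time zero", {
  fs <- 256
  n <- fs * 20
  lay <- layout_geodesic_129()[1:2, ]
  sig <- matrix(0, n, 2)
  t_ev <- 10
  sig[round(t_ev * fs) + 1L, ] <- 1        # impulse exactly at the event
  rec <- eeg_recording(sig, fs, lay)
  ev <- data.frame(t_cross = t_ev, direction = "smooth_to_rough")
  ep <- epoch_eeg(rec, ev)
  expect_equal(dim(ep$data), c(1, 2, 1024))
  i0 <- which(ep$data[1, 1, ] == 1)
  expect_equal(ep$times[i0], 0)
  # event at t = 10 covers 8..12 s of the recording
  expect_equal(ep$times[1], -2)
  # events too close to the edge are skipped with a warning
  ev2 <- data.frame(t_cross = c(1, t_ev), direction = "smooth_to_rough")
  expect_warning(ep2 <- epoch_eeg(rec, ev2), "skipped")
  expect_equal(dim(ep2$data)[1], 1)
  # overlapping epochs from events 3 s apart are both kept
  ev3 <- data.frame(t_cross = c(8, 11), direction = "rough_to_smooth")
  ep3 <- epoch_eeg(rec, ev3)
  expect_equal(dim(ep3$data)[1], 2)
})

test_that("the TF grid is 80 x 400 with half-open window bin counts", {
  set.seed(4)
  ep <- epoch_set(array(rnorm(2 * 1 * 1024), c(2, 1, 1024)),
                  c("smooth_to_rough", "rough_to_smooth"), 256)
  tf <- welch_tf(ep)
  expect_equal(dim(tf$power)[3:4], c(80L, 400L))
  expect_equal(tf$times[1], -2)
  expect_equal(tf$times[400], 1.99)
  # transition window 0..450 ms at 0.01 s pitch: 45 bins
  expect_equal(sum(tf$times >= 0 - 1e-9 & tf$times < 0.45 - 1e-9), 45L)
  expect_equal(sum(tf$times >= -0.65 - 1e-9 & tf$times < -0.2 - 1e-9), 45L)
  # alpha band on the 1 Hz grid: 5 bins
  expect_equal(sum(tf$freqs >= 8 & tf$freqs <= 12), 5L)
})

test_that("a sinusoid concentrates at its frequency bin", {
  fs <- 256
  times <- -2 + (0:1023) / fs
  x <- sin(2 * pi * 10 * times)
  ep <- make_ep2(x, fs)
  tf <- welch_tf(ep)
  mid <- which.min(abs(tf$times))
  spec <- tf$power[1, 1, , mid]
  expect_equal(which.max(spec), which(tf$freqs == 10))
  # > 20 dB above bins away from the mainlobe
  away <- spec[abs(tf$freqs - 10) > 3]
  expect_gt(10 * log10(spec[tf$freqs == 10] / max(away)), 20)
})

test_that("interior windows match a brute-force DFT periodogram", {
  set.seed(5)
  x <- rnorm(1024)
  ep <- make_ep2(x)
  tf <- welch_tf(ep, freqs = 1:80)
  for (tc in c(-1.3, 0, 0.77)) {
    b <- which.min(abs(tf$times - tc))
    for (f in c(3, 10, 41, 80)) {
      ref <- oracle_window_psd(x, ep$times, tf$times[b], f, 256)
      expect_equal(tf$power[1, 1, which(tf$freqs == f), b], ref,
                   tolerance = 1e-9)
    }
  }
  # edge (truncated) windows also match the oracle
  for (tc in c(-2, -1.8, 1.99)) {
    b <- which.min(abs(tf$times - tc))
    ref <- oracle_window_psd(x, ep$times, tf$times[b], 10, 256)
    expect_equal(tf$power[1, 1, 10, b], ref, tolerance = 1e-9)
  }
})

test_that("periodogram power sums to the tapered-signal variance", {
  # band-limited signal so the 1-80 Hz one-sided sum captures everything
  fs <- 256
  times <- -2 + (0:1023) / fs
  set.seed(6)
  x <- 0
  for (f in c(5, 12, 33, 61)) x <- x + runif(1, 0.5, 2) *
      sin(2 * pi * f * times + runif(1, 0, 2 * pi))
  ep <- make_ep2(x, fs)
  tf <- welch_tf(ep, freqs = 1:80)
  b <- which.min(abs(tf$times))
  j <- which(ep$times >= -0.5 - 1e-9 & ep$times < 0.5 - 1e-9)
  k <- (ep$times[j] + 0.5) * fs
  w <- 0.5 * (1 - cos(2 * pi * k / 255))
  tapered_var <- sum((x[j] * w)^2) / sum(w^2)
  expect_equal(sum(tf$power[1, 1, , b]), tapered_var, tolerance = 1e-6)
})

test_that("white-noise power is flat and proportional to variance", {
  set.seed(7)
  n_ep <- 200
  for (sigma in c(1, 2)) {
    dat <- array(rnorm(n_ep * 1 * 1024, 0, sigma), c(n_ep, 1, 1024))
    ep <- epoch_set(dat, rep(c("smooth_to_rough", "rough_to_smooth"),
                             n_ep / 2), 256)
    tf <- welch_tf(ep, freqs = seq(5, 75, by = 10))
    mid <- which.min(abs(tf$times))
    m <- apply(tf$power[, 1, , mid], 2, mean)
    # one-sided PSD of white noise: sigma^2 / (fs/2) per Hz
    expect_equal(mean(m), sigma^2 / 128, tolerance = 0.1)
    expect_lt(max(abs(m / mean(m) - 1)), 0.35)
  }
})

test_that("edge windows are unbiased in expected power", {
  set.seed(8)
  n_ep <- 300
  dat <- array(rnorm(n_ep * 1024), c(n_ep, 1, 1024))
  ep <- epoch_set(dat, rep(c("smooth_to_rough", "rough_to_smooth"),
                           n_ep / 2), 256)
  tf <- welch_tf(ep, freqs = c(10, 40))
  pw <- apply(tf$power[, 1, 1, ], 2, mean)
  edge <- mean(pw[c(1:5, 396:400)])
  interior <- mean(pw[150:250])
  expect_equal(edge / interior, 1, tolerance = 0.15)
})

test_that("sub-segmented Welch averaging is available and roughly agrees", {
  set.seed(9)
  times <- -2 + (0:1023) / 256
  x <- sin(2 * pi * 20 * times) + rnorm(1024, 0, 0.1)
  ep <- make_ep2(x)
  tf1 <- welch_tf(ep, freqs = c(10, 20, 40))
  tf3 <- welch_tf(ep, freqs = c(10, 20, 40), n_segments = 3)
  b <- which.min(abs(tf1$times))
  expect_equal(dim(tf3$power), dim(tf1$power))
  # the 20 Hz peak survives segmentation (coarser resolution spreads it)
  expect_gt(tf3$power[1, 1, 2, b], 10 * tf3$power[1, 1, 3, b])
})
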