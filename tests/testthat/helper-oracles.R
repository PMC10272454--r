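# Independent oracles: deliberately naive re-derivations used to check the
# package's optimised implementations. They share no code with R/.

# Brute-force single-window Hanning periodogram by direct DFT summation.
# Window: samples with t in [tc - L/2, tc + L/2), symmetric Hann evaluated
# at the sample's position within the ideal window, one-sided PSD scaling.
oracle_window_psd <- function(x, times, tc, freq, fs, window_len = 1) {
  win_n <- round(window_len * fs)
  j <- which(times >= tc - window_len / 2 - 1e-9 &
               times < tc + window_len / 2 - 1e-9)
  k <- (times[j] - (tc - window_len / 2)) * fs
  w <- 0.5 * (1 - cos(2 * pi * k / (win_n - 1)))
  xt <- x[j] * w
  acc <- 0 + 0i
  for (m in seq_along(xt))
    acc <- acc + xt[m] * exp(-2i * pi * freq * (m - 1) / fs)
  2 * Mod(acc)^2 / (fs * sum(w^2))
}

# Exact sign-flip permutation p-value for paired samples (two-sided,
# full enumeration; the identity pattern is part of the null set, so no
# add-one smoothing is needed).
oracle_exact_signflip_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- function(v) mean(v) / (stats::sd(v) / sqrt(n))
  t_obs <- abs(tstat(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_all <- apply(signs, 1, function(s) abs(tstat(s * d)))
  sum(t_all >= t_obs - 1e-12) / nrow(signs)
}

# Per-block means by direct loop (block-averaging oracle).
oracle_block_means <- function(x, k) {
  nb <- length(x) %/% k
  out <- numeric(nb)
  for (b in seq_len(nb)) out[b] <- mean(x[((b - 1) * k + 1):(b * k)])
  out
}

# Small epoch set with narrowband alpha plus white noise; the alpha
# amplitude is scaled by sqrt(1 + dpower) inside [0, 0.45) s.
make_alpha_epochs <- function(n_trials = 20, dpower = 0, fs = 256,
                              seed = 1, alpha_sd = 3, noise_sd = 1) {
  set.seed(seed)
  n_time <- 4 * fs
  times <- -2 + (seq_len(n_time) - 1) / fs
  dat <- array(0, c(n_trials, 1, n_time))
  g <- sqrt(1 + dpower)
  env <- ifelse(times >= 0 & times < 0.45, g, 1)
  for (tr in seq_len(n_trials)) {
    ph <- cumsum(rnorm(n_time, 0, 0.15)) + 2 * pi * 10 * times
    amp <- abs(1 + 0.3 * cumsum(rnorm(n_time, 0, 0.01)))
    a <- alpha_sd * amp * sin(ph)
    dat[tr, 1, ] <- a * env + rnorm(n_time, 0, noise_sd)
  }
  epoch_set(dat, rep(c("smooth_to_rough", "rough_to_smooth"),
                     length.out = n_trials), fs)
}

# Two-trial, one-channel epoch set holding the same signal in both trials
# (mind the array fill order: dim 1 = trials varies fastest).
make_ep2 <- function(x, fs = 256) {
  d <- array(0, c(2, 1, length(x)))
  d[1, 1, ] <- x
  d[2, 1, ] <- x
  epoch_set(d, c("smooth_to_rough", "rough_to_smooth"), fs)
}

expect_within <- function(object, lo, hi) {
  expect_gte(object, lo)
  expect_lte(object, hi)
}
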