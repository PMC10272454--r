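# Synthetic-session generator: kinematics, wrench round trips, EEG
# spectral realism, containers, and ground-truth manifests.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_blocks = 2, trials_per_block = 4,
                                 seed = 5), list(...))
  do.call(session_config, args)
}

test_that("jitter-free sweeps traverse the tile in exactly 4 s", {
  cfg <- small_cfg(speed_jitter = 0)
  kin <- simulate_kinematics(cfg)
  tr <- kin$trials
  for (i in seq_len(nrow(tr))) {
    i0 <- which(kin$time == tr$onset[i])
    i1 <- i0 + 4 * kin$sample_rate - 1
    expect_equal(abs(kin$x[i1] - kin$x[i0]), 100)
  }
  # far-edge crossing of the jitter-free sweep: 55 mm at 25 mm/s = 2.2 s
  expect_equal(tr$t_cross_true - tr$onset, rep(2.2, nrow(tr)),
               tolerance = 2e-3)
  expect_equal(tr$t_centre_true - tr$onset, rep(2.0, nrow(tr)),
               tolerance = 2e-3)
})

test_that("sweep directions alternate and blocks are counterbalanced", {
  cfg <- small_cfg()
  kin <- simulate_kinematics(cfg)
  tr <- kin$trials
  b1 <- tr$direction[tr$block == 1]
  expect_equal(b1, rep(c("smooth_to_rough", "rough_to_smooth"), 2))
  b2 <- tr$direction[tr$block == 2]
  expect_equal(b2, rep(c("rough_to_smooth", "smooth_to_rough"), 2))
  # jittered crossings stay near mid-sweep
  expect_within(min(tr$t_cross_true - tr$onset), 1.5, 2.5)
  expect_within(max(tr$t_cross_true - tr$onset), 1.5, 2.5)
})

test_that("the default session emits 120 trials, 60 per condition", {
  kin <- simulate_kinematics(session_config())
  expect_equal(nrow(kin$trials), 120L)
  tab <- table(kin$trials$direction)
  expect_equal(unname(tab[["smooth_to_rough"]]), 60L)
  expect_equal(unname(tab[["rough_to_smooth"]]), 60L)
})

test_that("noise-free wrench round-trips through the sensor stage", {
  cfg <- small_cfg(speed_jitter = 0, dropout_rate = 0,
                   wrench_noise = list(force_sd = 0, torque_sd = 0),
                   load_sd = 0)
  kin <- simulate_kinematics(cfg)
  wr <- simulate_wrench(kin, cfg)
  traj <- estimate_contact(block_average(wr$wrench, 100))
  # recovered x matches the kinematic x at block-average resolution
  keep <- traj$valid
  xk <- approx(kin$time, kin$x, traj$time[keep])$y
  expect_lt(max(abs(traj$x[keep] - xk)), 0.3)
  # detected transitions within one 100 Hz sample of ground truth
  ev <- detect_transitions(traj)
  expect_equal(nrow(ev), nrow(kin$trials))
  expect_lt(max(abs(ev$t_cross - kin$trials$t_cross_true)), 0.0101)
  expect_equal(ev$direction, kin$trials$direction)
})

test_that("a high-dropout trial is rejected by the 25% rule downstream", {
  cfg <- small_cfg(dropout_rate = 0)
  kin <- simulate_kinematics(cfg)
  wr <- simulate_wrench(kin, cfg)
  w <- wr$wrench
  # force 30% dropout inside trial 3
  on3 <- kin$trials$onset[3]
  sel <- which(w$time >= on3 & w$time < on3 + 1.2)
  w$missing[sel] <- TRUE
  traj <- estimate_contact(block_average(w, 100))
  rec <- epoch_trials(traj, kin$trials$onset)
  expect_false(rec$accepted[3])
  expect_gte(rec$missing_fraction[3], 0.25)
  expect_true(all(rec$accepted[-3]))
})

test_that("generated loads are recovered by the sensor stage", {
  cfg <- small_cfg(load_mean = 40, load_sd = 10)
  kin <- simulate_kinematics(cfg)
  wr <- simulate_wrench(kin, cfg)
  traj <- estimate_contact(block_average(wr$wrench, 100))
  rec <- epoch_trials(traj, kin$trials$onset)
  got <- vapply(seq_len(nrow(rec)), function(i)
    mean_load(traj, c(-2, 2), rec$t_cross[i]), 1)
  expect_equal(got, wr$loads, tolerance = 0.05)
})

test_that("simulated EEG has the configured 1/f slope and rhythm peaks", {
  cfg <- small_cfg()
  kin <- simulate_kinematics(cfg)
  # rhythm-free channel check: slope of the background
  cfg0 <- small_cfg(eeg = list(alpha_amp = 0, beta_amp = 0, white_sd = 0))
  rec0 <- simulate_eeg(cfg0, kin, seed = 9)
  g <- psd_slope(rec0$signals[, 1], rec0$sample_rate)
  expect_within(g, 0.8, 1.2)
  # rhythms appear at sensorimotor sites with the right peak frequencies
  rec <- simulate_eeg(cfg, kin, seed = 9)
  lay <- layout_geodesic_129()
  ch <- nearest_electrodes(lay, sensorimotor_sites()$left, 1)
  idx <- which(lay$label == ch)
  x <- rec$signals[, idx]
  seg <- 2048
  w <- seq(1, length(x) - seg, by = seg)
  psd <- rowMeans(sapply(w, function(s)
    Mod(fft(x[s:(s + seg - 1)]))^2))[1:200]
  f <- (seq_len(200) - 1) * rec$sample_rate / seg
  a_band <- mean(psd[f >= 9 & f <= 11])
  flank <- mean(psd[(f >= 6 & f <= 7.5) | (f >= 13 & f <= 15)])
  expect_gt(a_band / flank, 2)
})

test_that("injected ERD scales band amplitude by sqrt(1 + change)", {
  cfg <- small_cfg(speed_jitter = 0,
                   eeg = list(bg_sd = 0, beta_amp = 0, white_sd = 0))
  kin <- simulate_kinematics(cfg)
  lay <- layout_geodesic_129()
  tgt <- nearest_electrodes(lay, sensorimotor_sites()$left, 1)
  erd <- list(erd_spec(tgt, band = "alpha", window = c(0, 0.45),
                       relative_power_change = -0.4))
  rec0 <- simulate_eeg(cfg, kin, list(), lay, seed = 4)
  rec1 <- simulate_eeg(cfg, kin, erd, lay, seed = 4)
  idx <- which(lay$label == tgt)
  fs <- rec0$sample_rate
  tc <- kin$trials$t_cross_true[2]
  inwin <- function(r) {
    s <- r$signals[(round((tc + 0.1) * fs)):(round((tc + 0.35) * fs)), idx]
    mean(s^2)
  }
  expect_equal(inwin(rec1) / inwin(rec0), 0.6, tolerance = 0.02)
  # outside the gate the signals are identical
  out0 <- rec0$signals[1:1000, idx]
  out1 <- rec1$signals[1:1000, idx]
  expect_equal(out0, out1)
  # unknown electrodes are rejected
  expect_error(simulate_eeg(cfg, kin, list(erd_spec("nope")), lay),
               class = "config_error")
})

test_that("a null ERD (zero change) leaves the recording untouched", {
  cfg <- small_cfg(eeg = list(white_sd = 0))
  kin <- simulate_kinematics(cfg)
  lay <- layout_geodesic_129()
  erd0 <- list(erd_spec("E5", relative_power_change = 0))
  r0 <- simulate_eeg(cfg, kin, list(), lay, seed = 2)
  r1 <- simulate_eeg(cfg, kin, erd0, lay, seed = 2)
  expect_equal(r0$signals, r1$signals, tolerance = 1e-12)
})

test_that("EDF files round-trip signals within 16-bit quantisation", {
  set.seed(30)
  x <- matrix(rnorm(3000 * 4, 0, 30), 3000, 4)
  colnames(x) <- c("E1", "E2", "E3", "TRIG")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(x, f, sample_rate = 1000)
  back <- read_edf(f)
  expect_equal(back$sample_rate, 1000)
  expect_equal(back$labels, colnames(x))
  rng <- apply(x, 2, function(v) diff(range(v)))
  for (j in 1:4)
    expect_lt(max(abs(back$signals[, j] - x[, j])), rng[j] / 65535 + 1e-9)
})

test_that("generate_session writes a reproducible bundle", {
  cfg <- small_cfg(trials_per_block = 2)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  s1 <- generate_session(cfg, default_erd(), td1)
  s2 <- generate_session(cfg, default_erd(), td2)
  # same seed: byte-identical manifests and data files
  for (f in c("ground_truth.json", "wrench.csv", "onsets.csv")) {
    expect_identical(readLines(file.path(td1, f)),
                     readLines(file.path(td2, f)))
  }
  expect_identical(readBin(file.path(td1, "eeg.edf"), "raw", 1e7),
                   readBin(file.path(td2, "eeg.edf"), "raw", 1e7))
  truth <- jsonlite::read_json(file.path(td1, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$n_trials, 4)
  # manifest transitions match detection on the written wrench stream
  ws <- read_wrench_csv(file.path(td1, "wrench.csv"))
  traj <- estimate_contact(block_average(ws, 100))
  ev <- detect_transitions(traj)
  expect_equal(nrow(ev), 4)
  expect_lt(max(abs(ev$t_cross - truth$trials$t_cross_true)), 0.0101)
  # EDF holds the 129 channels plus trigger, pulses at trial onsets
  ed <- read_edf(file.path(td1, "eeg.edf"))
  expect_equal(ncol(ed$signals), 130)
  on1 <- truth$trials$onset[1]
  expect_gt(ed$signals[round(on1 * 1000) + 2, "TRIG"], 50)
})

test_that("the layout has 129 labelled unit-norm positions", {
  lay <- layout_geodesic_129()
  expect_equal(nrow(lay), 129)
  expect_equal(anyDuplicated(lay$label), 0L)
  expect_equal(sqrt(lay$x^2 + lay$y^2 + lay$z^2), rep(1, 129),
               tolerance = 1e-12)
  expect_true("Cz" %in% lay$label)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_layout(lay, f)
  expect_equal(read_layout(f)$z, lay$z, tolerance = 1e-12)
  # the packaged copy matches the generator
  pkg <- read_layout(system.file("extdata", "layout_geodesic129.tsv",
                                 package = "texchange"))
  expect_equal(pkg$x, lay$x, tolerance = 1e-9)
})
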