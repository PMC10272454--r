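# Wrench processing: block averaging, contact-point inversion, transition
# detection, trial quality rules, and load summaries.

make_wrench <- function(x_mm, y_mm, Fz, fs = 1000, missing = NULL) {
  n <- length(x_mm)
  w <- forward_wrench(x_mm, y_mm, Fz)
  wrench_series((seq_len(n) - 1) / fs, w$Fx, w$Fy, w$Fz, w$Tx, w$Ty, w$Tz,
                sample_rate = fs, missing = missing)
}

test_that("block averaging equals per-block means and propagates dropouts", {
  n <- 1000
  x <- rep(seq_len(100), each = 10) + rnorm(n)   # block-indexed + noise
  ws <- wrench_series((seq_len(n) - 1) / 1000, x, x, x, x, x, x,
                      sample_rate = 1000)
  ba <- block_average(ws, 100)
  expect_equal(ba$sample_rate, 100)
  expect_equal(ba$Fz, oracle_block_means(x, 10))
  # constant series stays constant
  wc <- wrench_series((seq_len(n) - 1) / 1000, rep(2, n), rep(2, n),
                      rep(2, n), rep(2, n), rep(2, n), rep(2, n),
                      sample_rate = 1000)
  expect_true(all(block_average(wc, 100)$Fx == 2))
  # partially missing block: mean over surviving samples only
  miss <- rep(FALSE, n); miss[1:4] <- TRUE
  wm <- wrench_series((seq_len(n) - 1) / 1000, x, x, x, x, x, x,
                      sample_rate = 1000, missing = miss)
  bam <- block_average(wm, 100)
  expect_equal(bam$Fz[1], mean(x[5:10]))
  # fully missing block is itself missing
  miss2 <- rep(FALSE, n); miss2[11:20] <- TRUE
  bm2 <- block_average(wrench_series((seq_len(n) - 1) / 1000, x, x, x, x,
                                     x, x, 1000, missing = miss2), 100)
  expect_true(bm2$missing[2])
  expect_error(block_average(ws, 300), class = "rate_error")
})

test_that("contact estimation inverts the forward wrench model", {
  # centred press produces no moment
  w0 <- make_wrench(rep(0, 10), rep(0, 10), rep(-0.3, 10))
  tr0 <- estimate_contact(w0)
  expect_equal(tr0$x, rep(0, 10))
  expect_equal(tr0$y, rep(0, 10))
  # stated example: r = (12.5, -4) mm under 0.5 N press
  w1 <- make_wrench(rep(12.5, 5), rep(-4, 5), rep(-0.5, 5))
  tr1 <- estimate_contact(w1)
  expect_equal(tr1$x, rep(12.5, 5))
  expect_equal(tr1$y, rep(-4, 5))
  expect_equal(tr1$load, rep(0.5 * 1000 / 9.81, 5))
  # below min_load: flagged invalid, position undefined
  wlo <- make_wrench(rep(10, 5), rep(0, 5), rep(-0.02, 5))  # ~2 g
  trlo <- estimate_contact(wlo, min_load = 5)
  expect_false(any(trlo$valid))
  expect_true(all(is.na(trlo$x)))
})

test_that("contact inversion is exact over random tile positions", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(1, -49, 49); y <- runif(1, -24, 24)
    Fz <- -runif(1, 0.1, 1)   # 10-100 g
    tr <- estimate_contact(make_wrench(rep(x, 3), rep(y, 3), rep(Fz, 3)))
    expect_lt(abs(tr$x[1] - x), 1e-9)
    expect_lt(abs(tr$y[1] - y), 1e-9)
  }
})

test_that("block averaging commutes with contact estimation for
           block-constant states", {
  set.seed(1)
  xs <- rep(runif(10, -40, 40), each = 10)
  ys <- rep(runif(10, -20, 20), each = 10)
  ws <- make_wrench(xs, ys, rep(-0.4, 100))
  a <- estimate_contact(block_average(ws, 100))
  expect_equal(a$x, xs[seq(1, 100, by = 10)])
  expect_equal(a$y, ys[seq(1, 100, by = 10)])
})

linear_traj <- function(xfun, fs = 100, t_end = 4) {
  t <- seq(0, t_end, by = 1 / fs)
  structure(list(time = t, x = xfun(t), y = rep(0, length(t)),
                 load = rep(40, length(t)), valid = rep(TRUE, length(t)),
                 sample_rate = fs), class = "contact_trajectory")
}

test_that("transition detection follows the far-edge-exit rule", {
  # x(t) = -50 + 25 t: solves x = +5 at t = 2.2, on the 100 Hz grid
  tr <- linear_traj(function(t) -50 + 25 * t)
  ev <- detect_transitions(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_cross, 2.2)
  expect_equal(ev$direction, "smooth_to_rough")
  # reverse sweep: symmetric time, opposite label
  rv <- detect_transitions(linear_traj(function(t) 50 - 25 * t))
  expect_equal(rv$t_cross, 2.2)
  expect_equal(rv$direction, "rough_to_smooth")
  # alternative crossing rules
  entry <- detect_transitions(tr, rule = "band-entry")
  expect_equal(entry$t_cross, 1.8)
  ctr <- detect_transitions(tr, rule = "centre-crossing")
  expect_equal(ctr$t_cross, 2.0)
})

test_that("incomplete band entries and never-entering paths yield no event", {
  # dips into the band and retreats on the same side
  dip <- linear_traj(function(t) -10 + 8 * sin(pi * t / 4))
  expect_equal(nrow(detect_transitions(dip)), 0L)
  flat <- linear_traj(function(t) rep(-30, length(t)))
  expect_equal(nrow(detect_transitions(flat)), 0L)
})

test_that("alternating sweeps give alternating events, one per sweep", {
  fs <- 100; n_sweeps <- 6
  t <- seq(0, 4 * n_sweeps - 1 / fs, by = 1 / fs)
  ph <- (t %% 8) / 4
  x <- ifelse(ph <= 1, -50 + 100 * ph, 50 - 100 * (ph - 1))
  tr <- structure(list(time = t, x = x, y = rep(0, length(t)),
                       load = rep(40, length(t)),
                       valid = rep(TRUE, length(t)), sample_rate = fs),
                  class = "contact_trajectory")
  ev <- detect_transitions(tr)
  expect_equal(nrow(ev), n_sweeps)
  expect_equal(ev$direction,
               rep(c("smooth_to_rough", "rough_to_smooth"), 3))
})

test_that("trial epoching applies the 25% missing rule", {
  fs <- 100
  t <- seq(0, 12 - 1 / fs, by = 1 / fs)
  x <- rep(-50 + 25 * (t %% 4), 1)        # same sweep every 4 s (teleports)
  valid <- rep(TRUE, length(t))
  valid[t >= 4 & t < 4 + 1.2] <- FALSE    # 30% of trial 2 missing
  tr <- structure(list(time = t, x = x, y = rep(0, length(t)),
                       load = rep(40, length(t)), valid = valid,
                       sample_rate = fs), class = "contact_trajectory")
  rec <- epoch_trials(tr, onsets = c(0, 4, 8))
  expect_true(rec$accepted[1])
  expect_false(rec$accepted[2])
  expect_equal(rec$missing_fraction[2], 0.3)
  # 20% missing with one transition stays accepted
  valid2 <- rep(TRUE, length(t))
  valid2[t >= 8 & t < 8.8] <- FALSE
  tr2 <- structure(list(time = t, x = x, y = rep(0, length(t)),
                        load = rep(40, length(t)), valid = valid2,
                        sample_rate = fs), class = "contact_trajectory")
  rec2 <- epoch_trials(tr2, onsets = c(0, 4, 8))
  expect_true(rec2$accepted[3])
  expect_equal(rec2$missing_fraction[3], 0.2)
  expect_equal(rec2$t_rel[1], 2.2)
  expect_error(epoch_trials(tr, onsets = 100), class = "bounds_error")
})

test_that("mean load averages valid samples in the window", {
  tr <- linear_traj(function(t) -50 + 25 * t)
  expect_equal(mean_load(tr, c(-0.65, -0.2), t_cross = 2.2), 40)
  # linear ramp averages to its midpoint
  tr$load <- seq(0, 100, length.out = length(tr$load))
  got <- mean_load(tr, c(0, 4.01), t_cross = 0)
  expect_equal(got, 50, tolerance = 1e-3)
  tr$valid[] <- FALSE
  expect_warning(out <- mean_load(tr, c(0, 1), t_cross = 2), "no valid")
  expect_true(is.na(out))
})

test_that("wrench CSV round-trips with empty fields for dropouts", {
  set.seed(3)
  n <- 50
  miss <- rep(FALSE, n); miss[c(5, 6)] <- TRUE
  ws <- wrench_series((seq_len(n) - 1) / 1000, rnorm(n), rnorm(n),
                      rnorm(n), rnorm(n), rnorm(n), rnorm(n),
                      sample_rate = 1000, missing = miss)
  f <- withr::local_tempfile(fileext = ".csv")
  write_wrench_csv(ws, f)
  expect_true(any(grepl(",,", readLines(f))))
  back <- read_wrench_csv(f)
  expect_equal(back$missing, miss)
  expect_equal(back$Fz[!miss], ws$Fz[!miss])
})
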