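# Synthetic experimental sessions.
#
# Emulates the study conditions: back-to-back 4 s finger sweeps at 2.5 cm/s
# across a 100 mm tile (blocks counterbalanced by starting texture), a
# six-axis wrench stream at 1,000 Hz driven by the planar-contact forward
# model with contact loads of tens of grams, and 129-channel EEG built from
# 1/f background plus spatially weighted alpha/beta sensorimotor rhythms,
# into which event-related power changes time-locked to the texture
# transitions can be injected with known magnitude.

#' Session configuration
#'
#' Defaults reproduce the task design: 4 blocks of 30 back-to-back 4 s
#' sweeps (120 trials, 60 per transition direction), cue speed 2.5 cm/s
#' over the 100 mm tile, contact loads around 40 g. EEG noise parameters
#' (`eeg`) set the 1/f exponent, rhythm amplitudes and topography widths.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block sweeps per block.
#' @param sweep_speed cue speed (cm/s).
#' @param sweep_duration trial length (s).
#' @param tile_length tile extent along x (mm).
#' @param load_mean,load_sd per-trial contact load distribution (gram-force).
#' @param speed_jitter relative speed jitter bound (0.1 = +-10%), smoothed.
#' @param dropout_rate per-sample probability of a missing wrench sample.
#' @param block_gap rest between blocks (s).
#' @param lead_in rest before the first and after the last block (s).
#' @param start_textures starting texture per block, recycled; the default
#'   counterbalances smooth/rough starts.
#' @param wrench_noise list: `force_sd` (N), `torque_sd` (N m).
#' @param eeg list of EEG generator parameters: `sample_rate` (Hz),
#'   `bg_sd` (uV), `gamma` (1/f exponent), `alpha_amp`, `beta_amp` (uV),
#'   `white_sd` (uV), `alpha_freq`, `beta_freq`, `alpha_bw`, `beta_bw`
#'   (Hz), `topo_sigma` (rad).
#' @param seed integer seed.
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_blocks = 4, trials_per_block = 30,
                           sweep_speed = 2.5, sweep_duration = 4,
                           tile_length = 100,
                           load_mean = 40, load_sd = 10,
                           speed_jitter = 0.1, dropout_rate = 0.01,
                           block_gap = 2, lead_in = 4,
                           start_textures = c("smooth", "rough",
                                              "rough", "smooth"),
                           wrench_noise = list(force_sd = 0.005,
                                               torque_sd = 5e-5),
                           eeg = list(),
                           seed = 1L) {
  if (abs(sweep_speed * 10 * sweep_duration - tile_length) > 1e-9)
    stop_tex("sweep_speed * sweep_duration must cover the tile length",
             "parameter_error")
  eeg_def <- list(sample_rate = 1000, bg_sd = 10, gamma = 1,
                  alpha_amp = 5, beta_amp = 3, white_sd = 2,
                  alpha_freq = 10, beta_freq = 20,
                  alpha_bw = 2, beta_bw = 4, topo_sigma = 0.35)
  eeg <- utils::modifyList(eeg_def, eeg)
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 sweep_speed = sweep_speed, sweep_duration = sweep_duration,
                 tile_length = tile_length, load_mean = load_mean,
                 load_sd = load_sd, speed_jitter = speed_jitter,
                 dropout_rate = dropout_rate, block_gap = block_gap,
                 lead_in = lead_in,
                 start_textures = rep_len(start_textures, n_blocks),
                 wrench_noise = wrench_noise, eeg = eeg, seed = seed),
            class = "session_config")
}

#' Injected event-related power change
#'
#' Describes a band-limited power change, time-locked to the texture
#' transition, applied at named electrodes. Amplitude is scaled by
#' `sqrt(1 + relative_power_change)` so the injected power change equals
#' the requested fraction exactly; the gating uses 50 ms raised-cosine
#' ramps to avoid spectral splatter.
#'
#' @param target_electrodes electrode labels.
#' @param band `"theta"`, `"alpha"` or `"beta"` (which generator rhythm is
#'   modulated).
#' @param window `c(onset, offset)` seconds relative to the transition.
#' @param relative_power_change fractional power change in (-1, 1);
#'   negative = desynchronisation.
#' @param condition_scope `"both"`, `"smooth_to_rough"` or
#'   `"rough_to_smooth"`.
#' @return an object of class `erd_spec`.
#' @export
erd_spec <- function(target_electrodes, band = "alpha", window = c(0, 0.45),
                     relative_power_change = -0.4,
                     condition_scope = c("both", "smooth_to_rough",
                                         "rough_to_smooth")) {
  condition_scope <- match.arg(condition_scope)
  if (window[1] >= window[2]) stop_tex("onset must precede offset",
                                       "parameter_error")
  if (abs(relative_power_change) >= 1)
    stop_tex("|relative_power_change| must be < 1", "parameter_error")
  structure(list(target_electrodes = target_electrodes, band = band,
                 window = window,
                 relative_power_change = relative_power_change,
                 condition_scope = condition_scope),
            class = "erd_spec")
}

# Smoothly jittered monotone progress curve over one sweep: returns values
# in [0, 1] at the given number of samples, exactly 0 and 1 at the ends.
sweep_progress <- function(n, jitter) {
  if (jitter == 0) return(seq(0, 1, length.out = n))
  raw <- stats::rnorm(ceiling(n / 50) + 8)
  sm <- stats::filter(raw, rep(1 / 5, 5), circular = TRUE)
  j <- stats::approx(seq_along(sm), as.numeric(sm), seq(1, length(sm),
                                                        length.out = n))$y
  j <- j / max(1e-12, stats::sd(j)) * (jitter / 2)
  j <- pmin(jitter, pmax(-jitter, j))
  v <- 1 + j
  p <- cumsum(v) - v[1]
  p / p[n]
}

#' Simulate fingertip kinematics for a session
#'
#' Back-to-back sweeps alternating direction across the tile, with smooth
#' within-sweep speed jitter (endpoints pinned so every sweep spans the
#' tile in exactly one trial duration). Between blocks and during lead-in
#' the finger rests on the tile at the current end.
#'
#' @param cfg a [session_config()].
#' @param sample_rate kinematic sample rate (Hz).
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return list with `time`, `x`, `y` (mm, tile-centre frame), `trials`
#'   (data.frame: trial, block, onset, direction, t_cross_true with the
#'   far-edge crossing time of the +-5 mm band, t_centre_true), `duration`.
#' @export
simulate_kinematics <- function(cfg, sample_rate = 1000, seed = cfg$seed) {
  with_seed(seed, {
    fs <- sample_rate
    half <- cfg$tile_length / 2
    n_sweep <- as.integer(cfg$sweep_duration * fs)
    blocks <- cfg$n_blocks
    tpb <- cfg$trials_per_block
    time_cursor <- 0
    x_all <- numeric(0)
    contact <- logical(0)
    trials <- list()
    rest <- function(dur, at_x) rep(at_x, as.integer(dur * fs))
    x_all <- c(x_all, rest(cfg$lead_in, -half))
    contact <- c(contact, rep(FALSE, as.integer(cfg$lead_in * fs)))
    time_cursor <- cfg$lead_in
    trial_no <- 0L
    for (b in seq_len(blocks)) {
      dir <- if (cfg$start_textures[b] == "smooth") 1 else -1
      # the stage is reoriented between blocks while the finger is lifted,
      # so each block simply starts at the cued end
      cur_x <- -dir * half
      for (tr in seq_len(tpb)) {
        trial_no <- trial_no + 1L
        p <- sweep_progress(n_sweep, cfg$speed_jitter)
        xs <- cur_x + dir * cfg$tile_length * p
        tt <- time_cursor + (seq_len(n_sweep) - 1L) / fs
        far <- if (dir > 0) which(xs >= 5)[1] else which(xs <= -5)[1]
        ctr <- if (dir > 0) which(xs >= 0)[1] else which(xs <= 0)[1]
        trials[[trial_no]] <- data.frame(
          trial = trial_no, block = b, onset = time_cursor,
          direction = if (dir > 0) "smooth_to_rough" else "rough_to_smooth",
          t_cross_true = tt[far], t_centre_true = tt[ctr])
        x_all <- c(x_all, xs)
        contact <- c(contact, rep(TRUE, n_sweep))
        time_cursor <- time_cursor + cfg$sweep_duration
        cur_x <- cur_x + dir * cfg$tile_length
        dir <- -dir
      }
      gap <- if (b < blocks) cfg$block_gap else cfg$lead_in
      x_all <- c(x_all, rest(gap, cur_x))
      contact <- c(contact, rep(FALSE, as.integer(gap * fs)))
      time_cursor <- time_cursor + gap
    }
    n <- length(x_all)
    y_raw <- stats::rnorm(ceiling(n / 200) + 4)
    y <- stats::approx(seq_along(y_raw), y_raw, seq(1, length(y_raw),
                                                    length.out = n))$y * 2
    list(time = (seq_len(n) - 1L) / fs, x = x_all, y = y,
         contact = contact, trials = do.call(rbind, trials),
         duration = n / fs, sample_rate = fs)
  })
}

#' Simulate the six-axis wrench stream for given kinematics
#'
#' Per-trial contact loads are drawn from the configured distribution and
#' vary slowly within trials; forces and torques follow the planar-contact
#' forward model ([forward_wrench()]) plus white sensor noise; samples drop
#' out independently at `dropout_rate`.
#'
#' @param kin output of [simulate_kinematics()].
#' @param cfg a [session_config()].
#' @param seed integer seed.
#' @return list with `wrench` (a [wrench_series()] at the kinematic rate)
#'   and `loads` (true per-trial mean loads, gram-force).
#' @export
simulate_wrench <- function(kin, cfg, seed = cfg$seed + 1L) {
  with_seed(seed, {
    n <- length(kin$time)
    fs <- kin$sample_rate
    # finger lifted off the tile outside blocks (stage reoriented in gaps)
    load <- ifelse(kin$contact, cfg$load_mean, 0)
    n_sweep <- as.integer(cfg$sweep_duration * fs)
    true_loads <- numeric(nrow(kin$trials))
    for (i in seq_len(nrow(kin$trials))) {
      L <- max(8, stats::rnorm(1, cfg$load_mean, cfg$load_sd))
      true_loads[i] <- L
      i0 <- as.integer(kin$trials$onset[i] * fs) + 1L
      slow <- stats::approx(seq_len(9), stats::rnorm(9),
                            seq(1, 9, length.out = n_sweep))$y
      load[i0:(i0 + n_sweep - 1L)] <- L * (1 + 0.05 * slow)
    }
    Fz <- -load * 9.81 / 1000
    vx <- c(0, diff(kin$x)) * fs
    Fx <- 0.4 * abs(Fz) * sign(vx)
    Fy <- stats::rnorm(n, 0, 0.01)
    w <- forward_wrench(kin$x, kin$y, Fz, Fx, Fy)
    ns <- cfg$wrench_noise
    if (ns$force_sd > 0) {
      w$Fx <- w$Fx + stats::rnorm(n, 0, ns$force_sd)
      w$Fy <- w$Fy + stats::rnorm(n, 0, ns$force_sd)
      w$Fz <- w$Fz + stats::rnorm(n, 0, ns$force_sd)
    }
    if (ns$torque_sd > 0) {
      w$Tx <- w$Tx + stats::rnorm(n, 0, ns$torque_sd)
      w$Ty <- w$Ty + stats::rnorm(n, 0, ns$torque_sd)
      w$Tz <- w$Tz + stats::rnorm(n, 0, ns$torque_sd)
    }
    miss <- stats::runif(n) < cfg$dropout_rate
    list(wrench = wrench_series(kin$time, w$Fx, w$Fy, w$Fz, w$Tx, w$Ty,
                                w$Tz, sample_rate = fs, missing = miss),
         loads = true_loads)
  })
}

# FFT-shaped Gaussian noise with a given one-sided amplitude profile
# shape(f); returned with unit variance when normalize = TRUE. Synthesis
# runs at the next 5-smooth length (fast FFT) and truncates, which leaves
# the process stationary.
shaped_noise <- function(n, fs, shape, normalize = TRUE) {
  n2 <- next_fast_len(n)
  f <- abs(fft_freq(n2)) * fs / n2
  amp <- shape(f)
  z <- stats::fft(stats::rnorm(n2))
  x <- Re(stats::fft(z * amp, inverse = TRUE))[seq_len(n)] / n2
  if (normalize) {
    s <- stats::sd(x)
    if (s > 0) x <- x / s
  }
  x
}

# Smallest integer >= n whose prime factors are all in {2, 3, 5}.
next_fast_len <- function(n) {
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Raised-cosine gated amplitude envelope: value `g` inside [t0, t1] with
# `ramp`-second cosine flanks, 1 elsewhere. Vectorised over `t`.
gate_envelope <- function(t, t0, t1, g, ramp = 0.05) {
  env <- rep(1, length(t))
  core <- t >= t0 + ramp & t <= t1 - ramp
  env[core] <- g
  up <- t >= t0 & t < t0 + ramp
  env[up] <- 1 + (g - 1) * 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  dn <- t > t1 - ramp & t <= t1
  env[dn] <- 1 + (g - 1) * 0.5 * (1 - cos(pi * (t1 - t[dn]) / ramp))
  env
}

#' Simulate a 129-channel EEG recording for a session
#'
#' Per channel: `1/f^gamma` background plus narrowband alpha (10 Hz) and
#' beta (20 Hz) rhythms with Gaussian spatial weights centred on the
#' left/right sensorimotor sites (alpha) and the central midline (beta),
#' plus white measurement noise. For every trial and every [erd_spec()]
#' whose scope matches the trial's condition, the band's amplitude at the
#' target electrodes is scaled by `sqrt(1 + relative_power_change)` inside
#' the spec's window relative to the trial's true transition time.
#'
#' @param cfg a [session_config()].
#' @param kin output of [simulate_kinematics()].
#' @param erd list of [erd_spec()] objects (possibly empty).
#' @param layout layout data.frame.
#' @param seed integer seed.
#' @param amp_scale,erd_scale per-participant multipliers for rhythm
#'   amplitude and ERD magnitude (used by group simulations).
#' @return an [eeg_recording()] whose `$events` holds the trial table.
#' @export
simulate_eeg <- function(cfg, kin, erd = list(), layout = layout_geodesic_129(),
                         seed = cfg$seed + 2L, amp_scale = 1, erd_scale = 1) {
  bad <- unlist(lapply(erd, function(e)
    setdiff(e$target_electrodes, layout$label)))
  if (length(bad) > 0)
    stop_tex(paste("ERD electrodes not in layout:",
                   paste(unique(bad), collapse = ", ")), "config_error")
  with_seed(seed, {
    p <- cfg$eeg
    fs <- p$sample_rate
    n <- as.integer(round(kin$duration * fs))
    t <- (seq_len(n) - 1L) / fs
    nch <- nrow(layout)
    pos <- as.matrix(layout[, c("x", "y", "z")])
    pos <- pos / sqrt(rowSums(pos^2))
    sites <- sensorimotor_sites()
    angw <- function(site, sigma) {
      a <- acos(pmin(1, pmax(-1, pos %*% site)))
      exp(-a^2 / (2 * sigma^2))
    }
    w_alpha <- angw(sites$left, p$topo_sigma) + angw(sites$right, p$topo_sigma)
    w_beta <- angw(sites$central, p$topo_sigma + 0.05)
    bg_shape <- function(f) ifelse(f < 0.5, 0, 1 / pmax(f, 1)^(p$gamma / 2))
    nb_shape <- function(f0, bw) {
      s <- bw / 2.355
      function(f) exp(-(f - f0)^2 / (2 * s^2))
    }
    band_w <- list(alpha = w_alpha, beta = w_beta)
    band_amp <- list(alpha = p$alpha_amp, beta = p$beta_amp)
    band_shape <- list(alpha = nb_shape(p$alpha_freq, p$alpha_bw),
                       beta = nb_shape(p$beta_freq, p$beta_bw))
    # precompute per-band, per-target-electrode envelopes
    envs <- list(alpha = NULL, beta = NULL)
    for (e in erd) {
      g <- sqrt(1 + max(-0.95, min(0.95, e$relative_power_change * erd_scale)))
      env <- rep(1, n)
      sel <- if (e$condition_scope == "both") rep(TRUE, nrow(kin$trials))
             else kin$trials$direction == e$condition_scope
      for (tc in kin$trials$t_cross_true[sel])
        env <- env * gate_envelope(t, tc + e$window[1], tc + e$window[2], g)
      ee <- envs[[e$band]] %||% list()
      for (ch in e$target_electrodes)
        ee[[ch]] <- if (is.null(ee[[ch]])) env else ee[[ch]] * env
      envs[[e$band]] <- ee
    }
    sig <- matrix(0, n, nch)
    for (ch in seq_len(nch)) {
      x <- shaped_noise(n, fs, bg_shape) * p$bg_sd
      for (bn in c("alpha", "beta")) {
        a <- band_amp[[bn]] * amp_scale * band_w[[bn]][ch]
        if (a < 1e-3) next
        nb <- shaped_noise(n, fs, band_shape[[bn]]) * a
        env <- envs[[bn]][[layout$label[ch]]]
        if (!is.null(env)) nb <- nb * env
        x <- x + nb
      }
      sig[, ch] <- x + stats::rnorm(n, 0, p$white_sd)
    }
    eeg_recording(sig, fs, layout, reference = "Cz", events = kin$trials)
  })
}

#' Generate a full synthetic session on disk
#'
#' Writes the wrench CSV, the EEG as an EDF file (scalp channels plus a
#' `TRIG` channel carrying 10 ms visual-onset pulses), the trial-onset
#' list, the sensor layout, and a JSON ground-truth manifest (true
#' transition times and directions, per-trial loads, injected ERD and
#' noise parameters). Fully reproducible from the seed.
#'
#' @param cfg a [session_config()].
#' @param erd list of [erd_spec()]s.
#' @param dir output directory (created if needed).
#' @param layout layout data.frame.
#' @return invisibly, `list(paths = <written files>, truth = <ground
#'   truth>)`.
#' @export
generate_session <- function(cfg, erd = list(), dir,
                             layout = layout_geodesic_129()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kin <- simulate_kinematics(cfg)
  wr <- simulate_wrench(kin, cfg)
  rec <- simulate_eeg(cfg, kin, erd, layout)
  fs <- rec$sample_rate
  trig <- numeric(nrow(rec$signals))
  for (o in kin$trials$onset) {
    i0 <- as.integer(o * fs) + 1L
    trig[i0:min(length(trig), i0 + as.integer(0.01 * fs))] <- 100
  }
  paths <- list(
    wrench = file.path(dir, "wrench.csv"),
    eeg = file.path(dir, "eeg.edf"),
    onsets = file.path(dir, "onsets.csv"),
    layout = file.path(dir, "layout.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_wrench_csv(wr$wrench, paths$wrench)
  write_edf(cbind(rec$signals, TRIG = trig), paths$eeg, fs,
            labels = c(colnames(rec$signals), "TRIG"))
  utils::write.csv(kin$trials[, c("trial", "block", "onset", "direction")],
                   paths$onsets, row.names = FALSE)
  write_layout(layout, paths$layout)
  truth <- list(
    config = unclass(cfg)[c("n_blocks", "trials_per_block", "sweep_speed",
                            "sweep_duration", "load_mean", "load_sd",
                            "dropout_rate", "seed")],
    n_trials = nrow(kin$trials),
    n_per_condition = as.list(table(kin$trials$direction)),
    trials = kin$trials,
    loads = wr$loads,
    erd = lapply(erd, unclass),
    eeg_noise = cfg$eeg)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(list(paths = paths, truth = truth))
}
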