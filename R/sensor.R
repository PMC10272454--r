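# Six-axis touch-sensor processing.
#
# The tile sits on a six-axis load cell; the finger's contact point is the
# centre of pressure of the measured wrench. Frame convention (fixed here
# because only the measurement, not the formula, is given upstream):
# right-handed, z up, tile surface at z = 0, compression Fz < 0. For a
# contact at r = (x, y, 0) with force F, the torque is T = r x F, so with a
# dominant normal force x = -Ty/Fz and y = Tx/Fz.

#' Six-axis wrench time series
#'
#' @param time sample times (s), strictly increasing and uniform.
#' @param Fx,Fy,Fz forces (N).
#' @param Tx,Ty,Tz torques (N m).
#' @param sample_rate nominal rate (Hz); checked against `time`.
#' @param missing logical per-sample dropout flag; samples with any NA in
#'   the six channels are also treated as missing.
#' @return an object of class `wrench_series`.
#' @export
wrench_series <- function(time, Fx, Fy, Fz, Tx, Ty, Tz,
                          sample_rate = 1000, missing = NULL) {
  n <- length(time)
  chans <- list(Fx = Fx, Fy = Fy, Fz = Fz, Tx = Tx, Ty = Ty, Tz = Tz)
  stopifnot(all(vapply(chans, length, 1L) == n))
  if (n > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop_tex("time must be strictly increasing", "parameter_error")
    if (abs(stats::median(dt) - 1 / sample_rate) > 1e-6 / sample_rate)
      stop_tex("sample spacing inconsistent with sample_rate", "parameter_error")
  }
  miss <- missing %||% rep(FALSE, n)
  miss <- miss | Reduce(`|`, lapply(chans, is.na))
  structure(c(list(time = time), chans,
              list(sample_rate = sample_rate, missing = miss)),
            class = "wrench_series")
}

#' Forward wrench model for a planar contact
#'
#' Builds the wrench a load cell would measure for a fingertip pressing at
#' `(x, y)` on the tile surface: `T = r x F` with `r = (x, y, 0)`. This is
#' the model that [estimate_contact()] inverts; it also drives the
#' synthetic-session generator.
#'
#' @param x,y contact position (mm, tile-centre frame).
#' @param Fz normal force (N, compression negative).
#' @param Fx,Fy tangential forces (N).
#' @return data.frame with columns Fx, Fy, Fz, Tx, Ty, Tz.
#' @export
forward_wrench <- function(x, y, Fz, Fx = 0, Fy = 0) {
  xm <- x / 1000; ym <- y / 1000
  data.frame(Fx = Fx, Fy = Fy, Fz = Fz,
             Tx = ym * Fz,
             Ty = -xm * Fz,
             Tz = xm * Fy - ym * Fx)
}

#' Block-average a wrench series to a lower rate
#'
#' Each output sample is the arithmetic mean of a contiguous block of input
#' samples; missing samples are excluded from the mean, and a block with all
#' samples missing is itself marked missing.
#'
#' @param series a [wrench_series()].
#' @param target_rate output rate (Hz); must divide the input rate.
#' @return a [wrench_series()] at `target_rate`.
#' @export
block_average <- function(series, target_rate = 100) {
  k <- series$sample_rate / target_rate
  if (abs(k - round(k)) > 1e-9)
    stop_tex("target_rate must divide sample_rate", "rate_error")
  k <- as.integer(round(k))
  n <- length(series$time)
  nb <- n %/% k
  idx <- seq_len(nb * k)
  g <- rep(seq_len(nb), each = k)
  ok <- !series$missing[idx]
  cnt <- as.vector(rowsum(as.numeric(ok), g))
  avg1 <- function(v) {
    x <- v[idx]; x[!ok] <- 0
    s <- as.vector(rowsum(x, g))
    ifelse(cnt > 0, s / cnt, NA_real_)
  }
  wrench_series(
    time = as.vector(rowsum(series$time[idx], g)) / k,
    Fx = avg1(series$Fx), Fy = avg1(series$Fy), Fz = avg1(series$Fz),
    Tx = avg1(series$Tx), Ty = avg1(series$Ty), Tz = avg1(series$Tz),
    sample_rate = target_rate,
    missing = cnt == 0)
}

#' Estimate the fingertip contact trajectory from a wrench series
#'
#' Centre-of-pressure inversion `x = -Ty/Fz`, `y = Tx/Fz` (mm), with the
#' contact load `|Fz| * 1000/9.81` in gram-force. Samples whose load falls
#' below `min_load` (or that are missing) are flagged invalid rather than
#' divided through.
#'
#' @param series a [wrench_series()], normally at 100 Hz after
#'   [block_average()].
#' @param min_load minimum load (gram-force) for a valid contact sample.
#' @return an object of class `contact_trajectory` with fields `time`, `x`,
#'   `y` (mm), `load` (g), `valid`, `sample_rate`.
#' @export
estimate_contact <- function(series, min_load = 5) {
  g_per_N <- 1000 / 9.81
  load <- abs(series$Fz) * g_per_N
  valid <- !series$missing & !is.na(load) & load >= min_load
  x <- y <- rep(NA_real_, length(load))
  x[valid] <- -series$Ty[valid] / series$Fz[valid] * 1000
  y[valid] <- series$Tx[valid] / series$Fz[valid] * 1000
  structure(list(time = series$time, x = x, y = y, load = load,
                 valid = valid, sample_rate = series$sample_rate),
            class = "contact_trajectory")
}

#' Detect texture-transition events from a contact trajectory
#'
#' The transition region spans `[-band_halfwidth, +band_halfwidth]` mm about
#' the tile centre on the x axis. One event is emitted per complete monotone
#' traversal of the band; incomplete entries (retreating on the entry side)
#' produce nothing. Three timepoint conventions are supported for the event
#' time: the first sample at/beyond the far edge (`"far-edge-exit"`,
#' default, i.e. the finger has fully traversed the transition), the first
#' sample inside the band (`"band-entry"`), or the first sample past the
#' centre (`"centre-crossing"`).
#'
#' @param traj a `contact_trajectory`.
#' @param band_halfwidth half-width of the transition band (mm).
#' @param rule which instant within the traversal to report.
#' @param max_gap contact interruption (s) after which traversal tracking
#'   restarts; a crossing requires continuous contact.
#' @return data.frame with columns `t_cross` (s), `direction`
#'   (`"smooth_to_rough"` for travel toward positive x, else
#'   `"rough_to_smooth"`).
#' @export
detect_transitions <- function(traj, band_halfwidth = 5,
                               rule = c("far-edge-exit", "band-entry",
                                        "centre-crossing"),
                               max_gap = 0.5) {
  rule <- match.arg(rule)
  keep <- traj$valid
  t <- traj$time[keep]; x <- traj$x[keep]
  hw <- band_halfwidth
  events <- list()
  # `out`: side of the band the finger last sat strictly outside of;
  # during a pending traversal, entry/centre/exit milestones use weak
  # inequalities, so a sample exactly on an edge counts as reaching it
  out <- NA_integer_
  enter_i <- centre_i <- NA_integer_
  t_prev <- -Inf
  for (i in seq_along(x)) {
    xi <- x[i]
    if (t[i] - t_prev > max_gap) {          # contact was lost: start fresh
      out <- if (xi < -hw) -1L else if (xi > hw) 1L else NA_integer_
      enter_i <- centre_i <- NA_integer_
      t_prev <- t[i]
      next
    }
    t_prev <- t[i]
    if (is.na(out)) {
      if (xi < -hw) out <- -1L else if (xi > hw) out <- 1L
      next
    }
    d <- -out                                # travel direction to traverse
    if (d * xi >= hw) {                      # reached the far edge: event
      exit_i <- i
      ti <- switch(rule,
                   "far-edge-exit" = exit_i,
                   "band-entry" = if (is.na(enter_i)) exit_i else enter_i,
                   "centre-crossing" = if (is.na(centre_i)) exit_i
                                       else centre_i)
      events[[length(events) + 1L]] <- data.frame(
        t_cross = t[ti],
        direction = if (d == 1L) "smooth_to_rough" else "rough_to_smooth",
        stringsAsFactors = FALSE)
      out <- d
      enter_i <- centre_i <- NA_integer_
    } else if (d * xi < -hw) {               # back strictly outside: retreat
      enter_i <- centre_i <- NA_integer_
    } else {
      if (is.na(enter_i) && d * xi >= -hw) enter_i <- i
      if (is.na(centre_i) && d * xi >= 0) centre_i <- i
    }
  }
  if (length(events) == 0)
    return(data.frame(t_cross = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Epoch a session into trials and apply quality rules
#'
#' One record per visual trial onset. A trial is accepted when fewer than
#' `reject_fraction` of its samples are missing/invalid and exactly one
#' texture transition falls inside its window; the latency from onset to
#' transition is stored as `t_rel`.
#'
#' @param traj a `contact_trajectory`.
#' @param onsets trial onset times (s).
#' @param duration trial length (s).
#' @param reject_fraction maximum tolerated fraction of missing samples.
#' @param ... passed to [detect_transitions()].
#' @return data.frame with one row per trial: `trial`, `onset`,
#'   `missing_fraction`, `n_transitions`, `t_cross`, `direction`, `t_rel`,
#'   `accepted`.
#' @export
epoch_trials <- function(traj, onsets, duration = 4, reject_fraction = 0.25,
                         ...) {
  t_end <- max(traj$time)
  if (any(onsets > t_end))
    stop_tex("trial onset beyond recording end", "bounds_error")
  ev <- detect_transitions(traj, ...)
  out <- lapply(seq_along(onsets), function(i) {
    o <- onsets[i]
    win <- traj$time >= o & traj$time < o + duration
    mf <- if (any(win)) mean(!traj$valid[win]) else 1
    inwin <- ev$t_cross >= o & ev$t_cross < o + duration
    k <- sum(inwin)
    tc <- if (k >= 1) ev$t_cross[inwin][1] else NA_real_
    dir <- if (k >= 1) ev$direction[inwin][1] else NA_character_
    data.frame(trial = i, onset = o, missing_fraction = mf,
               n_transitions = k, t_cross = tc, direction = dir,
               t_rel = tc - o,
               accepted = mf < reject_fraction && k == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean contact load in a window around the transition
#'
#' @param traj a `contact_trajectory`.
#' @param window `c(t0, t1)` in seconds relative to `t_cross`; samples with
#'   `t0 <= t - t_cross < t1` contribute.
#' @param t_cross transition time (s).
#' @return mean load over valid samples (gram-force); `NA` with a warning
#'   when the window holds no valid sample.
#' @export
mean_load <- function(traj, window, t_cross) {
  rel <- traj$time - t_cross
  sel <- traj$valid & rel >= window[1] & rel < window[2]
  if (!any(sel)) {
    warning("no valid samples in load window; returning NA")
    return(NA_real_)
  }
  mean(traj$load[sel])
}

#' Read / write a wrench CSV
#'
#' Delimited text with header `time,Fx,Fy,Fz,Tx,Ty,Tz`; missing samples are
#' encoded as empty fields in the six wrench columns.
#'
#' @param path CSV path.
#' @param sample_rate nominal rate of the stored series (Hz).
#' @return [read_wrench_csv()]: a [wrench_series()].
#' @export
read_wrench_csv <- function(path, sample_rate = 1000) {
  d <- utils::read.csv(path)
  wrench_series(d$time, d$Fx, d$Fy, d$Fz, d$Tx, d$Ty, d$Tz,
                sample_rate = sample_rate)
}

#' @rdname read_wrench_csv
#' @param series a [wrench_series()] to write; missing samples are blanked.
#' @export
write_wrench_csv <- function(series, path) {
  d <- data.frame(time = series$time, Fx = series$Fx, Fy = series$Fy,
                  Fz = series$Fz, Tx = series$Tx, Ty = series$Ty,
                  Tz = series$Tz)
  d[series$missing, -1] <- NA
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}
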