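# Parameter-recovery and calibration experiments built on the pipeline.

#' Default injected-ERD specification for recovery experiments
#'
#' Alpha desynchronisation of -40% power during the transition window at
#' the three electrodes nearest each sensorimotor hand area (bilateral, six
#' electrodes), mirroring the topography of the effect the pipeline is
#' designed to detect.
#'
#' @param layout sensor layout.
#' @param k electrodes per hemisphere.
#' @param relative_power_change injected fractional power change.
#' @return list of one [erd_spec()].
#' @export
default_erd <- function(layout = layout_geodesic_129(), k = 3L,
                        relative_power_change = -0.4) {
  sites <- sensorimotor_sites()
  targets <- c(nearest_electrodes(layout, sites$left, k),
               nearest_electrodes(layout, sites$right, k))
  list(erd_spec(targets, band = "alpha", window = c(0, 0.45),
                relative_power_change = relative_power_change,
                condition_scope = "both"))
}

#' End-to-end ERD recovery experiment
#'
#' Simulates a group of participants with a known alpha desynchronisation
#' injected at bilateral sensorimotor electrodes, runs the complete
#' pipeline (sensor fusion, preprocessing, Welch time-frequency, robust z,
#' electrode-wise permutation statistics on the pre-vs-transition alpha
#' contrast), and scores recovery against ground truth:
#' sensitivity = fraction of injected electrodes flagged significant,
#' false-positive rate = fraction of non-injected analysed electrodes
#' flagged significant.
#'
#' Sessions use 2 blocks of 6 sweeps per participant (12 trials, 6 per
#' direction) — a reduced trial count at the full electrode montage and
#' permutation depth.
#'
#' @param n_participants simulated group size.
#' @param n_perm permutation repetitions.
#' @param relative_power_change injected alpha power change.
#' @param seed master seed.
#' @param trials_per_block,n_blocks session size per participant.
#' @param freqs frequencies computed (must cover the analysis bands).
#' @param progress print per-participant progress.
#' @return list: `sensitivity`, `fp_rate`, `targets`, `results` (the full
#'   [run_pipeline()] output), `alpha_stats` (electrode table for the
#'   scored contrast).
#' @export
erd_recovery_experiment <- function(n_participants = 30, n_perm = 5000,
                                    relative_power_change = -0.4,
                                    seed = 42L,
                                    trials_per_block = 6, n_blocks = 2,
                                    freqs = 1:30, progress = FALSE) {
  layout <- layout_geodesic_129()
  erd <- default_erd(layout,
                     relative_power_change = relative_power_change)
  cfg <- run_config(
    session = session_config(n_blocks = n_blocks,
                             trials_per_block = trials_per_block,
                             seed = seed),
    erd = erd,
    n_participants = n_participants,
    freqs = freqs,
    n_perm = n_perm,
    contrasts = "pre_vs_transition",
    seed = seed)
  res <- run_pipeline(cfg, layout, progress = progress)
  es <- res$electrode_stats
  a <- es[es$band == "alpha" & es$contrast == "pre_vs_transition", ]
  targets <- erd[[1]]$target_electrodes
  is_target <- a$electrode %in% targets
  list(sensitivity = mean(a$significant[is_target]),
       fp_rate = mean(a$significant[!is_target]),
       targets = targets,
       alpha_stats = a,
       results = res)
}

#' Type-I error calibration of the permutation stage
#'
#' Draws both paired conditions i.i.d. standard normal (a global null) for
#' many electrodes and measures the electrode-wise rejection rate of the
#' sign-flip permutation test at level `alpha`.
#'
#' @param n_electrodes number of simulated null electrodes.
#' @param n_participants participants per electrode.
#' @param n_perm permutation repetitions.
#' @param alpha nominal level.
#' @param seed seed.
#' @return list: `rejection_rate`, `n_electrodes`.
#' @export
type1_calibration <- function(n_electrodes = 1000, n_participants = 30,
                              n_perm = 5000, alpha = 0.05, seed = 1L) {
  AB <- with_seed(seed, list(
    a = matrix(stats::rnorm(n_participants * n_electrodes),
               n_participants, n_electrodes),
    b = matrix(stats::rnorm(n_participants * n_electrodes),
               n_participants, n_electrodes)))
  p <- permutation_paired(AB$a, AB$b, n_perm = n_perm, seed = seed + 1L)
  list(rejection_rate = mean(p$p_perm < alpha, na.rm = TRUE),
       n_electrodes = n_electrodes)
}

#' Spectral slope of a signal's power spectrum
#'
#' Log-log linear fit of the Welch PSD over `band`, excluding the rhythm
#' bands, used to check the 1/f realism of simulated EEG.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band fit range (Hz).
#' @param exclude list of `c(lo, hi)` bands left out of the fit.
#' @return the fitted exponent gamma (positive for 1/f^gamma decay).
#' @export
psd_slope <- function(x, fs, band = c(2, 40),
                      exclude = list(c(7, 13), c(15, 25))) {
  seg <- as.integer(fs)                     # 1 s segments, 50% overlap
  starts <- seq(1L, length(x) - seg + 1L, by = seg %/% 2L)
  w <- hann_taper(seg)
  acc <- 0
  for (s in starts)
    acc <- acc + Mod(stats::fft(x[s:(s + seg - 1L)] * w))^2
  psd <- acc / length(starts)
  f <- (seq_along(psd) - 1L) * fs / seg
  keep <- f >= band[1] & f <= band[2]
  for (ex in exclude) keep <- keep & !(f >= ex[1] & f <= ex[2])
  fit <- stats::lm(log(psd[keep]) ~ log(f[keep]))
  -unname(stats::coef(fit)[2])
}
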