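# End-to-end orchestration: synthetic session -> sensor fusion -> EEG
# time-frequency -> group statistics, with a reproducible run manifest.

#' Full-run configuration
#'
#' Every analysis parameter defaults to the study's stated value: +-5 mm
#' transition band, 25% missing-sample rejection, 4 s trials, -2..2 s
#' epochs, 1 s windows at 0.01 s hop, 1-80 Hz at 1 Hz, theta/alpha/beta
#' bands, -650..-200 ms and 0..450 ms analysis windows, 5,000 permutations
#' at alpha = 0.05, and the 5-MAD trial outlier rule.
#'
#' @param session a [session_config()] describing each participant's
#'   session (per-participant seeds are derived from `seed`).
#' @param erd list of [erd_spec()]s injected into every participant.
#' @param n_participants number of simulated participants.
#' @param bands,windows band and window definitions.
#' @param freqs frequencies computed by [welch_tf()].
#' @param band_halfwidth,crossing_rule,reject_fraction sensor-stage
#'   parameters (see [detect_transitions()], [epoch_trials()]).
#' @param epoch_window EEG epoch bounds (s, relative to transition).
#' @param n_perm,alpha permutation-stage parameters.
#' @param outlier_threshold trial-level z exclusion threshold (MAD units).
#' @param pool robust-z pooling (see [robust_z()]).
#' @param adjacency_max_angle neighbour threshold (rad) or `NULL` to derive.
#' @param contrasts which group contrasts to run.
#' @param run_stats compute the group statistics stage.
#' @param amp_sigma,erd_sigma log-normal sigma of per-participant rhythm
#'   amplitude and ERD magnitude scaling.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(session = session_config(), erd = list(),
                       n_participants = 30,
                       bands = standard_bands(),
                       windows = standard_windows(),
                       freqs = 1:80,
                       band_halfwidth = 5,
                       crossing_rule = "far-edge-exit",
                       reject_fraction = 0.25,
                       epoch_window = c(-2, 2),
                       n_perm = 5000, alpha = 0.05,
                       outlier_threshold = 5,
                       pool = "epoch",
                       adjacency_max_angle = NULL,
                       contrasts = c("pre_vs_transition", "s2r_vs_r2s"),
                       run_stats = TRUE,
                       amp_sigma = 0.2, erd_sigma = 0.15,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' Serialisation is lossless: `load_run_config(save_run_config(cfg, f))`
#' reproduces `cfg`.
#' @param cfg a [run_config()].
#' @param path YAML path.
#' @return [load_run_config()]: the restored `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  x <- rapply(unclass(cfg), unclass, how = "replace")
  x$session <- unclass(cfg$session)
  x$erd <- lapply(cfg$erd, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$session <- do.call(session_config, x$session)
  x$erd <- lapply(x$erd, function(e) do.call(erd_spec, e))
  x$epoch_window <- as.numeric(x$epoch_window)
  x$freqs <- as.numeric(x$freqs)
  x$bands <- lapply(x$bands, as.numeric)
  x$windows <- lapply(x$windows, as.numeric)
  do.call(run_config, x)
}

#' Process one participant's session through the sensor and EEG stages
#'
#' Simulates (or accepts) one session and carries it to trial-level
#' band/window z values and window loads: block-averaged contact
#' trajectory, transition detection, trial quality filtering,
#' preprocessing, transition-locked epoching, Welch time-frequency,
#' robust z, band/window averaging.
#'
#' @param cfg a [run_config()].
#' @param participant participant identifier.
#' @param seed participant-level seed.
#' @param amp_scale,erd_scale participant multipliers (see
#'   [simulate_eeg()]).
#' @param layout sensor layout.
#' @return list: `bw` (trial-level band/window table), `trials` (sensor
#'   trial records), `loads` (`pre`/`transition` mean gram-force),
#'   `n_accepted` per condition.
#' @export
process_participant <- function(cfg, participant, seed,
                                amp_scale = 1, erd_scale = 1,
                                layout = layout_geodesic_129()) {
  s <- cfg$session
  kin <- simulate_kinematics(s, seed = seed)
  wr <- simulate_wrench(kin, s, seed = seed + 1L)
  rec <- simulate_eeg(s, kin, cfg$erd, layout, seed = seed + 2L,
                      amp_scale = amp_scale, erd_scale = erd_scale)
  traj <- estimate_contact(block_average(wr$wrench, 100))
  trials <- epoch_trials(traj, kin$trials$onset,
                         duration = s$sweep_duration,
                         reject_fraction = cfg$reject_fraction,
                         band_halfwidth = cfg$band_halfwidth,
                         rule = cfg$crossing_rule)
  acc <- trials[trials$accepted, ]
  prep <- preprocess(rec)
  ep <- epoch_eeg(prep, acc, tmin = cfg$epoch_window[1],
                  tmax = cfg$epoch_window[2], participant = participant)
  tf <- welch_tf(ep, freqs = cfg$freqs)
  tfz <- robust_z(tf, pool = cfg$pool)
  bw <- band_window_average(tfz, cfg$bands, cfg$windows)
  loads <- vapply(cfg$windows, function(w) {
    mean(vapply(acc$t_cross, function(tc)
      suppressWarnings(mean_load(traj, w, tc)), 1), na.rm = TRUE)
  }, 1)
  list(bw = bw, trials = trials, loads = loads,
       n_accepted = table(factor(acc$direction,
                                 c("smooth_to_rough", "rough_to_smooth"))))
}

# participant x electrode matrix of aggregated band/window values.
# Cells whose trials were all removed by the outlier rule fall back to the
# unfiltered mean (and are counted in the manifest).
bw_matrix <- function(bw_list, band, window, electrodes, condition = NULL,
                      threshold = 5) {
  rows <- lapply(bw_list, function(b) {
    d <- b[b$band == band & b$window == window, ]
    if (!is.null(condition)) d <- d[d$condition == condition, ]
    vals <- vapply(electrodes, function(e) {
      v <- d$value[d$channel == e]
      vf <- suppressWarnings(remove_outliers(v, threshold))
      if (length(vf) == 0) mean(v, na.rm = TRUE) else mean(vf)
    }, 1)
    vals
  })
  m <- do.call(rbind, rows)
  colnames(m) <- electrodes
  m
}

#' Run the full analysis pipeline on simulated participants
#'
#' Executes the stages in dependency order for each participant
#' ([process_participant()]), then the group statistics: for each band and
#' contrast, an electrode-wise paired sign-flip permutation test, spatial
#' clustering of significant electrodes, follow-up paired t-tests with
#' Bonferroni correction over clusters, plus the paired load comparison.
#'
#' Contrasts: `pre_vs_transition` compares the pre-transition and
#' transition windows on trials pooled over both sweep directions;
#' `s2r_vs_r2s` compares the two directions within the transition window.
#'
#' @param cfg a [run_config()].
#' @param layout sensor layout (reference electrode excluded from
#'   statistics).
#' @param progress print per-participant progress.
#' @return list with `electrode_stats` (per band x contrast x electrode),
#'   `clusters` (follow-up table), `load` (paired t result),
#'   `participants` (acceptance counts and loads), and `manifest`.
#' @export
run_pipeline <- function(cfg, layout = layout_geodesic_129(),
                         progress = FALSE) {
  t_start <- Sys.time()
  np <- cfg$n_participants
  scales <- with_seed(cfg$seed, list(
    amp = exp(stats::rnorm(np, 0, cfg$amp_sigma)),
    erd = exp(stats::rnorm(np, 0, cfg$erd_sigma))))
  res <- vector("list", np)
  for (p in seq_len(np)) {
    res[[p]] <- process_participant(cfg, participant = sprintf("P%02d", p),
                                    seed = cfg$seed + 101L * p,
                                    amp_scale = scales$amp[p],
                                    erd_scale = scales$erd[p],
                                    layout = layout)
    if (progress)
      message(sprintf("participant %d/%d: %d accepted trials", p, np,
                      sum(res[[p]]$trials$accepted)))
  }
  bw_list <- lapply(res, `[[`, "bw")
  electrodes <- setdiff(layout$label, "Cz")
  part_tab <- data.frame(
    participant = sprintf("P%02d", seq_len(np)),
    n_accepted_s2r = vapply(res, function(r) unname(r$n_accepted[1]), 1),
    n_accepted_r2s = vapply(res, function(r) unname(r$n_accepted[2]), 1),
    load_pre = vapply(res, function(r) r$loads[["pre"]], 1),
    load_transition = vapply(res, function(r) r$loads[["transition"]], 1))

  out <- list(participants = part_tab)
  out$load <- load_compare(part_tab$load_pre, part_tab$load_transition)

  if (cfg$run_stats) {
    adj <- adjacency_graph(layout[layout$label %in% electrodes, ],
                           cfg$adjacency_max_angle)
    stats_rows <- list(); clus_rows <- list()
    for (band in names(cfg$bands)) {
      for (ct in cfg$contrasts) {
        if (ct == "pre_vs_transition") {
          A <- bw_matrix(bw_list, band, "pre", electrodes,
                         threshold = cfg$outlier_threshold)
          B <- bw_matrix(bw_list, band, "transition", electrodes,
                         threshold = cfg$outlier_threshold)
        } else {
          A <- bw_matrix(bw_list, band, "transition", electrodes,
                         condition = "smooth_to_rough",
                         threshold = cfg$outlier_threshold)
          B <- bw_matrix(bw_list, band, "transition", electrodes,
                         condition = "rough_to_smooth",
                         threshold = cfg$outlier_threshold)
        }
        perm <- permutation_paired(A, B, n_perm = cfg$n_perm,
                                   seed = cfg$seed + 17L)
        perm$significant <- !is.na(perm$p_perm) & perm$p_perm < cfg$alpha
        cl <- cluster_significant(perm, cfg$alpha, adj)
        fu <- followup_t(A, B, cl)
        perm$cluster <- NA_integer_
        for (i in seq_along(cl))
          perm$cluster[perm$electrode %in% cl[[i]]] <- i
        perm$band <- band; perm$contrast <- ct
        stats_rows[[paste(band, ct)]] <- perm
        if (nrow(fu) > 0) {
          fu$band <- band; fu$contrast <- ct
          clus_rows[[paste(band, ct)]] <- fu
        }
      }
    }
    out$electrode_stats <- do.call(rbind, c(stats_rows,
                                            make.row.names = FALSE))
    out$clusters <- if (length(clus_rows) > 0)
      do.call(rbind, c(clus_rows, make.row.names = FALSE))
    else followup_t(matrix(0, 2, 1), matrix(0, 2, 1), list())
  }

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("texchange")),
    seed = cfg$seed,
    n_participants = np,
    n_perm = cfg$n_perm, alpha = cfg$alpha,
    session = cfg$session[c("n_blocks", "trials_per_block", "sweep_speed",
                            "sweep_duration", "load_mean", "load_sd",
                            "dropout_rate")],
    erd = lapply(cfg$erd, unclass),
    freqs = range(cfg$freqs),
    pool = cfg$pool,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  class(out) <- "texchange_results"
  out
}

#' Human-readable summary of pipeline results
#'
#' Per band and contrast: significant electrodes, clusters with their
#' follow-up t/df/p (raw and Bonferroni), and the load comparison. A pure
#' function of the result tables: regenerating the report from the same
#' results gives identical text.
#'
#' @param results output of [run_pipeline()].
#' @return character vector of report lines (also printed invisibly usable
#'   via `writeLines`).
#' @export
report <- function(results) {
  ln <- c("== texture-change pipeline report ==", "")
  es <- results$electrode_stats
  if (!is.null(es)) {
    for (band in unique(es$band)) {
      for (ct in unique(es$contrast)) {
        d <- es[es$band == band & es$contrast == ct, ]
        sig <- d$electrode[d$significant]
        ln <- c(ln, sprintf("[%s / %s]", band, ct))
        if (length(sig) == 0) {
          ln <- c(ln, "  no significant electrodes")
        } else {
          ln <- c(ln, sprintf("  significant electrodes (p < %g): %s",
                              results$manifest$alpha,
                              paste(sig, collapse = ", ")))
          cl <- results$clusters
          cl <- cl[cl$band == band & cl$contrast == ct, , drop = FALSE]
          for (i in seq_len(nrow(cl)))
            ln <- c(ln, sprintf(
              "  cluster %d (%s): t(%d) = %.2f, p = %.4g, p_bonf = %.4g",
              cl$cluster[i], cl$electrodes[i], cl$df[i], cl$t[i], cl$p[i],
              cl$p_bonferroni[i]))
        }
      }
    }
    ln <- c(ln, "")
  }
  ld <- results$load
  ln <- c(ln, sprintf(
    "load: pre %.2f g vs transition %.2f g, t(%d) = %.2f, p = %.3f",
    ld$mean_pre, ld$mean_trans, ld$df, ld$t, ld$p))
  ln
}
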