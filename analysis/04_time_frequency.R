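#!/usr/bin/env Rscript
# EEG stage on the simulated session: preprocess (0.5-100 Hz band-pass,
# 48-52 Hz notch, 256 Hz, common average), epoch -2..2 s around the
# detected transitions, compute the 400-point sliding Welch spectrogram at
# 1 Hz resolution, robust-z normalise, and average into the theta/alpha/
# beta x pre/transition cells. Run 02 and 03 first.

library(texchange)
stopifnot(file.exists("results/session/eeg.edf"),
          file.exists("results/events.csv"))

edf <- read_edf("results/session/eeg.edf")
layout <- read_layout("results/session/layout.tsv")
rec <- eeg_recording(edf$signals[, layout$label], edf$sample_rate, layout)
events <- read.csv("results/events.csv")
acc <- events[events$accepted, ]
acc$t_cross <- acc$t_cross_s

message(sprintf("preprocessing %d channels at %d Hz...",
                ncol(rec$signals), rec$sample_rate))
prep <- preprocess(rec)
ep <- epoch_eeg(prep, acc, participant = "demo")
message(sprintf("%d epochs x %d channels x %d samples",
                dim(ep$data)[1], dim(ep$data)[2], dim(ep$data)[3]))

tf <- welch_tf(ep, freqs = 1:30)
tfz <- robust_z(tf)
bw <- band_window_average(tfz)
write.csv(bw, "results/band_window_trials.csv", row.names = FALSE)

agg <- aggregate_band_windows(bw)
write.csv(agg, "results/band_window_means.csv", row.names = FALSE)

truth <- jsonlite::read_json("results/session/ground_truth.json",
                             simplifyVector = TRUE)
tgt <- unlist(truth$erd$target_electrodes)
a <- agg[agg$band == "alpha", ]
on_t <- a$channel %in% tgt
message(sprintf(
  "alpha z at injected electrodes: pre %+.2f -> transition %+.2f",
  mean(a$value[on_t & a$window == "pre"]),
  mean(a$value[on_t & a$window == "transition"])))
message(sprintf(
  "alpha z elsewhere:              pre %+.2f -> transition %+.2f",
  mean(a$value[!on_t & a$window == "pre"]),
  mean(a$value[!on_t & a$window == "transition"])))
message("wrote results/band_window_trials.csv, results/band_window_means.csv")
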