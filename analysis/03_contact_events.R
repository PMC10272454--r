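#!/usr/bin/env Rscript
# Sensor fusion on the simulated session: block-average the 1,000 Hz
# wrench stream to 100 Hz, invert it to a fingertip trajectory, detect
# +-5 mm transition-band crossings, epoch into 4 s trials with the 25%
# missing-sample rule, and summarise contact load. Run 02 first.

library(texchange)
stopifnot(file.exists("results/session/wrench.csv"))

wrench <- read_wrench_csv("results/session/wrench.csv")
onsets <- read.csv("results/session/onsets.csv")
truth <- jsonlite::read_json("results/session/ground_truth.json",
                             simplifyVector = TRUE)

traj <- estimate_contact(block_average(wrench, 100))
trials <- epoch_trials(traj, onsets$onset)
message(sprintf("%d/%d trials accepted (%.0f%% mean dropout)",
                sum(trials$accepted), nrow(trials),
                100 * mean(trials$missing_fraction)))

acc <- trials[trials$accepted, ]
err <- abs(acc$t_cross - truth$trials$t_cross_true[acc$trial])
message(sprintf("transition timing vs ground truth: max |error| %.1f ms",
                1000 * max(err)))

loads <- data.frame(
  trial = acc$trial,
  pre = vapply(acc$t_cross, function(tc)
    mean_load(traj, c(-0.65, -0.20), tc), 1),
  transition = vapply(acc$t_cross, function(tc)
    mean_load(traj, c(0, 0.45), tc), 1))
message(sprintf("window loads: pre %.1f g, transition %.1f g",
                mean(loads$pre), mean(loads$transition)))

events <- data.frame(trial = trials$trial, onset_s = trials$onset,
                     t_cross_s = trials$t_cross,
                     direction = trials$direction,
                     accepted = trials$accepted,
                     missing_fraction = trials$missing_fraction)
write.csv(events, "results/events.csv", row.names = FALSE)
write.csv(loads, "results/window_loads.csv", row.names = FALSE)
message("wrote results/events.csv, results/window_loads.csv")
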