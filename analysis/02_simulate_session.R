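#!/usr/bin/env Rscript
# Generate one complete synthetic session on disk: 1,000 Hz six-axis
# wrench CSV, 129-channel EEG (EDF, with a trigger channel), trial onsets,
# sensor layout, and the ground-truth manifest. A bilateral alpha
# desynchronisation of -40% power is injected during the transition
# window so later stages have a known effect to recover.
#
# The demo session is reduced to 2 blocks x 10 sweeps to stay light; the
# full task design (4 x 30) is `session_config()`'s default.

library(texchange)

cfg <- session_config(n_blocks = 2, trials_per_block = 10, seed = 42)
erd <- default_erd()
message(sprintf("injecting %+.0f%% alpha power at: %s",
                100 * erd[[1]]$relative_power_change,
                paste(erd[[1]]$target_electrodes, collapse = ", ")))

ses <- generate_session(cfg, erd, "results/session")
message(sprintf("session written under results/session (%d trials, %s)",
                ses$truth$n_trials,
                paste(names(ses$truth$n_per_condition),
                      unlist(ses$truth$n_per_condition),
                      collapse = ", ")))
message(sprintf("true mean load %.1f g; EEG %.1f s at %d Hz",
                mean(ses$truth$loads),
                file.size(ses$paths$eeg) / (130 * 2 * 1000),
                cfg$eeg$sample_rate))
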