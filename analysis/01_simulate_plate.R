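#!/usr/bin/env Rscript
# Simulate a sunitinib dose-response plate with ground truth and write it
# to disk as the raw input for the downstream analysis steps: one 2-page
# 16-bit TIFF per field (channel 1 Hoechst, channel 2 alpha-actinin),
# plus layout and truth CSVs.

suppressMessages(library(sarcscreen))

out_dir <- "results/plate_dose_response"
seed <- 20240915L

groups <- list(
  group_spec("DMSO", dose_uM = 0, healthy_fraction = 1.00, is_control = TRUE),
  group_spec("SUN_0.3uM", dose_uM = 0.3, healthy_fraction = 0.65),
  group_spec("SUN_1uM", dose_uM = 1, healthy_fraction = 0.15),
  group_spec("SUN_3uM", dose_uM = 3, healthy_fraction = 0.01))

# a desk-scale plate: 3 wells/group x 4 fields keeps the raw images small;
# the scoring and statistics steps accept any plate written in this format
cfg <- sim_config(groups, mode = "sarcomere_60x", rng_seed = seed,
                  wells_per_group = 3L, fields_per_well = 4L)

paths <- generate_plate(cfg, out_dir)
cat("plate written to", out_dir, "\n")
cat("  fields:", length(paths$images), "\n")
cat("  layout:", paths$layout, "\n")
truth <- read.csv(paths$well_truth)
cat("  per-well true healthy fractions:\n")
print(truth)
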