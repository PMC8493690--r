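#!/usr/bin/env Rscript
# Dose-response inference on the per-well HSI table from
# 02_segment_and_score.R: Bartlett gate, then Williams' or
# Shirley-Williams' step-down trend test at one-sided alpha 0.025, plus
# the two-group control-vs-top-dose comparison at alpha 0.05.

suppressMessages(library(sarcscreen))

wells <- read.csv("results/wells.csv")
layout <- read.csv("results/plate_dose_response/layout.csv")
d <- merge(wells, layout, by = "well")

ctrl <- d$hsi[d$group_label == "DMSO"]
dg <- d[d$group_label != "DMSO", ]
dg <- dg[order(dg$dose_uM), ]
doses <- split(dg$hsi, factor(dg$group_label, levels = unique(dg$group_label)))

series <- dose_series(ctrl, doses, direction = "decreasing")
gate <- heterogeneity_gate(series)
cat("heterogeneity gate:", gate$test,
    if (!is.na(gate$p)) sprintf("(Bartlett p = %.3f)", gate$p) else "", "\n")

res <- trend_test(series)
print(res$table, digits = 3)

top <- names(doses)[length(doses)]
tg <- two_group_test(ctrl, doses[[top]])
cat(sprintf("\ncontrol vs %s: %s test, p = %.4g (%s at alpha 0.05)\n",
            top, tg$method, tg$p,
            if (tg$significant) "significant" else "not significant"))

write.csv(res$table, "results/trend_test.csv", row.names = FALSE)
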