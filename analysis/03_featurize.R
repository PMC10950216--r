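#!/usr/bin/env Rscript
# Step 3 — sliding-window feature matrix and 7-day labels.
#
# One prediction frame per (patient, lab date): four weekly look-back
# windows of lab/medication/observation aggregates plus static registry
# features; the label is positive iff an AKI episode opens within the next
# 7 days. Missing lab values stay missing (the learner handles them
# natively); frames inside the 14 days after a first episode are flagged
# ineligible for evaluation.

suppressMessages({library(akireason); library(data.table)})

det <- readRDS("results/detection.rds")
frames <- assemble_matrix(det$filtered, det$episodes)
saveRDS(frames, "results/frames.rds")
fwrite(attr(frames, "specs"), "results/feature_specs.csv")

cat(sprintf("%d frames x %d features; positive fraction %.3f; %.1f%% eligible\n",
            nrow(frames), length(attr(frames, "feature_names")),
            mean(frames$label), 100 * mean(frames$eligible)))
per_pat <- frames[, .N, by = patient_id]
cat(sprintf("frames per patient: median %d (IQR %d-%d)\n",
            as.integer(median(per_pat$N)),
            as.integer(quantile(per_pat$N, 0.25)),
            as.integer(quantile(per_pat$N, 0.75))))
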