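#!/usr/bin/env Rscript
# Step 2 — cohort filters and KDIGO episode detection.
#
# Applies the study's exclusions (ESRD at baseline, no creatinine after ICI
# start, censored alive before 3 months), then detects and stages
# creatinine-defined AKI episodes (+0.3 mg/dL within 48 h or 1.5x within
# 7 days; stages 1-3 by the 7-day peak) and applies the 14-day multi-event
# rule to index each patient's first episode.

suppressMessages({library(akireason); library(data.table)})

cohort <- read_cohort("results/cohort")
filt <- apply_cohort_filters(cohort)
episodes <- detect_cohort_episodes(filt$cohort)
firsts <- attr(episodes, "first_episodes")

fwrite(filt$exclusions, "results/exclusions.csv")
fwrite(episodes, "results/episodes.csv")
fwrite(firsts, "results/first_episodes.csv")
saveRDS(list(filtered = filt$cohort, episodes = episodes),
        "results/detection.rds")

cat(sprintf("excluded %d of %d patients:\n", nrow(filt$exclusions),
            nrow(cohort$registry)))
print(table(filt$exclusions$reason))
n <- nrow(filt$cohort$registry)
cat(sprintf("AKI: %d of %d analyzable patients (%.1f%%); stages: %s\n",
            nrow(firsts), n, 100 * nrow(firsts) / n,
            paste(names(table(firsts$stage)), table(firsts$stage),
                  sep = "=", collapse = ", ")))
cat(sprintf("%d patients multi-event-excluded from the clustered set\n",
            sum(firsts$multi_event_excluded)))
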