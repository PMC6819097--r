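#!/usr/bin/env Rscript
# Stage 3: auditory oddball functional-localizer design.
#
# 1260 stimuli (80% standards, 10% contour deviants, 10% interval deviants),
# same-type deviant pairs 2400-4800 ms apart, and the balanced extraction of
# 126 standards (each flanked by >= 5 standards) for implicit GLM modeling.

suppressPackageStartupMessages(library(tonetrans))

set.seed(1003)
design <- generate_design(1260)
ex <- extract_balanced_standards(design)
dir.create("results", showWarnings = FALSE)
write_events_table(design, "results/oddball_events.tsv")

counts <- table(design$condition)
cat("Design:", counts[["STD"]], "standards,", counts[["C_DEV"]],
    "contour deviants,", counts[["I_DEV"]], "interval deviants.\n")
cat("Balanced extraction:", length(ex$modeled),
    "standards modeled implicitly,", length(ex$remaining), "remaining.\n")
dev <- design[!is.na(design$pair_id), ]
gaps <- vapply(split(dev$onset_ms, dev$pair_id), diff, numeric(1))
cat("Deviant pair gaps span", min(gaps), "-", max(gaps), "ms.\n")
cat("Run duration:", round(max(design$onset_ms) / 60000, 1), "min.\n")
cat("Wrote results/oddball_events.tsv\n")
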