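#!/usr/bin/env Rscript
# Stage 2 — compliance and preparation.
#
# A prompt counts as completed only when every item was answered; the
# inclusion rule keeps participants with at least 50 of the 84 scheduled
# prompts. The pooled z-scoring record is written for later inversion.

library(lcvar)

out_dir <- "results/analysis"
panel <- read_long_table(file.path(out_dir, "panel.csv"))

comp <- compute_compliance(panel)
write.csv(data.frame(participant_id = names(comp), compliance = comp),
          file.path(out_dir, "compliance.csv"), row.names = FALSE)

filtered <- filter_compliance(panel, min_completed = 50)
write_long_table(filtered, file.path(out_dir, "panel_filtered.csv"))
write.csv(standardize_panel(filtered)$scaling,
          file.path(out_dir, "scaling.csv"), row.names = FALSE)

message(sprintf("compliance: median %.2f, range %.2f-%.2f; retained %d of %d participants",
                median(comp), min(comp), max(comp),
                length(panel_participants(filtered)),
                length(panel_participants(panel))))
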