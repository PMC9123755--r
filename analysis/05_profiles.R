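#!/usr/bin/env Rscript
# Stage 5 — descriptive surfaces of the selected solution.
#
# Coefficient heatmap matrices per cluster (model scale) and per-cluster
# daytime courses of the raw items (observed, pre-imputation values), with
# a figure of the daytime courses.

library(lcvar)

out_dir <- "results/analysis"

memb <- read.csv(file.path(out_dir, "membership.csv"),
                 colClasses = c(participant_id = "character"))
labels <- setNames(memb$cluster, memb$participant_id)
raw <- read_long_table(file.path(out_dir, "panel_filtered.csv"))

course <- daytime_means(raw, labels)
tab <- daytime_course_table(course)
write.csv(tab, file.path(out_dir, "daytime_means.csv"), row.names = FALSE)

# Rebuild the selected fit's heatmaps from the stored coefficient tables.
K <- max(labels)
for (k in seq_len(K)) {
  C <- as.matrix(read.csv(file.path(out_dir, sprintf("coef_cluster_%d.csv", k)),
                          row.names = 1))
  lag_cols <- grep("_lag", colnames(C))
  write.csv(C[, lag_cols], file.path(out_dir, sprintf("heatmap_cluster_%d.csv", k)))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  tab$cluster <- factor(tab$cluster)
  p <- ggplot(tab, aes(beep, mean, colour = cluster)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "beep (daytime)", y = "mean (0-100 scale)",
         title = "Per-cluster daytime courses") +
    theme_minimal()
  ggsave(file.path(out_dir, "daytime_courses.pdf"), p, width = 7, height = 5)
}

appetite <- subset(tab, variable == "item_3" & cluster == 1)
message(sprintf("hunger-like item course (cluster 1): %s",
                paste(sprintf("%.1f", appetite$mean), collapse = " ")))
message("wrote daytime_means.csv and per-cluster heatmap matrices")
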