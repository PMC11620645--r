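#!/usr/bin/env Rscript
# Partition genes through the variance/interaction/additive cascade, derive
# the genotype clusters (G1-G3), spatiotemporal template classes (C1-C8)
# and interaction clusters (I1-I9), and score everything against the
# generator's truth table.

suppressMessages(library(colonyexpr))

src <- "results/synthetic"
res <- run_pipeline(
  pipeline_config(counts_path = file.path(src, "counts.csv"),
                  design_path = file.path(src, "design.csv"),
                  dialect = "csv_matrix", out_dir = src, seed = 20240))

cls <- res$classification
message("partition: ", paste(sprintf("%s=%d", names(table(cls$status)),
                                     table(cls$status)), collapse = ", "))

truth <- read.csv(file.path(src, "truth.csv"))
rec <- partition_recovery(cls, truth)
write.csv(rec, file.path(src, "recovery.csv"), row.names = FALSE)
for (i in seq_len(nrow(rec)))
  message(sprintf("  %-18s n=%4d  sensitivity=%s  FPR=%s", rec$class[i],
                  rec$n[i],
                  ifelse(is.na(rec$sensitivity[i]), "-",
                         sprintf("%.3f", rec$sensitivity[i])),
                  ifelse(is.na(rec$false_positive_rate[i]), "-",
                         sprintf("%.3f", rec$false_positive_rate[i]))))

message("G clusters: ", paste(names(table(cls$cluster_G)),
                              table(cls$cluster_G), collapse = ", "))
message("C classes:  ", paste(names(table(cls$cluster_C)),
                              table(cls$cluster_C), collapse = ", "))
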