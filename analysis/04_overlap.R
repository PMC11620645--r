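#!/usr/bin/env Rscript
# Cluster-overlap statistics. First on the synthetic run: cross-tabulate the
# spatiotemporal template classes against the genotype clusters for genes
# responding additively to both factors and test independence exactly.
# Then the published worked examples: the printed 8x3 overlap table and the
# 2x2 responder-overlap reconstruction from the printed totals.

suppressMessages(library(colonyexpr))

src <- "results/synthetic"
cls <- read.csv(file.path(src, "classification.csv"))
both <- cls[cls$status == "additive_both", ]
ct <- crosstab(setNames(both$cluster_C, both$gene_id),
               setNames(both$cluster_G, both$gene_id))
message(sprintf("synthetic C x G crosstab over %d both-responsive genes:",
                sum(ct)))
print(ct)
ft <- fisher_rxc(ct, seed = 20240)
message(sprintf("synthetic C x G independence: p = %.3g (%s)",
                ft$p_value, ft$method))

t2 <- as.matrix(read.csv(system.file("extdata", "cluster_overlap_published.csv",
                                     package = "colonyexpr"), row.names = 1))
ft2 <- fisher_rxc(t2)
message(sprintf("printed 8x3 overlap table: %d genes, exact two-tailed p = %.3g",
                sum(t2), ft2$p_value))

totals <- read.csv(system.file("extdata", "responder_overlap_totals.csv",
                               package = "colonyexpr"))
cnt <- setNames(totals$count, totals$quantity)
for (reading in c("inclusive", "exclusive")) {
  tab <- both_factor_table(cnt[["spatio_responders"]],
                           cnt[["genotype_responders"]],
                           cnt[["both_responders"]], cnt[["gene_universe"]],
                           reading = reading)
  f <- fisher_2x2(tab, tail = "one_greater")
  message(sprintf("responder overlap (%s reading): one-tailed p = %.3g, OR = %.1f",
                  reading, f$p_value, f$odds_ratio))
}

out <- data.frame(test = c("synthetic_CxG", "printed_8x3"),
                  p = c(ft$p_value, ft2$p_value),
                  method = c(ft$method, ft2$method))
write.csv(out, file.path(src, "overlap_tests.csv"), row.names = FALSE)
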