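#!/usr/bin/env Rscript
# Dose-response processing for the three mitotic inhibitors: growth
# percent, GI50/TGI per cell line, high- vs low-MNAI Mann-Whitney
# comparison, inter-drug GI50 correlation, a pairwise-combination check on
# one sensitive and one resistant line, and siRNA screen statistics.

suppressPackageStartupMessages(library(mitonet))

data_dir <- "results/data"
out <- "results"

plates <- read_plates(file.path(data_dir, "plates.csv"))
curves <- curves_from_plates(plates)
gt <- gi50_table(curves)
write.table(gt, file.path(out, "gi50_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

mn <- read.delim(file.path(out, "mnai_1.tsv"))
rows <- list()
for (drug in unique(gt$drug)) {
  sub <- merge(gt[gt$drug == drug, ], mn[, c("sample_id", "tertile")],
               by.x = "cell_line", by.y = "sample_id")
  sub <- sub[sub$tertile %in% c("high", "low"), ]
  cmp <- compare_response_groups(sub$gi50, as.character(sub$tertile))
  rows[[drug]] <- data.frame(drug = drug, U = cmp$U, p = cmp$p,
                             median_high_nM = unname(cmp$medians["high"]),
                             median_low_nM = unname(cmp$medians["low"]))
  cat(sprintf("%s: median GI50 %.0f nM (high MNAI) vs %.0f nM (low), Mann-Whitney p = %.2g\n",
              drug, cmp$medians["high"], cmp$medians["low"], cmp$p))
}
write.table(do.call(rbind, rows), file.path(out, "gi50_group_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cors <- correlate_drug_responses(gt)
write.table(cors, file.path(out, "drug_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Inter-drug log10 GI50 Pearson r:",
    paste(sprintf("%s~%s %.2f", cors$drug_a, cors$drug_b, cors$r),
          collapse = ", "), "\n")

# combination check: most sensitive vs most resistant line, drug pair 1+2
g1 <- gt[gt$drug == unique(gt$drug)[1], ]
sens <- g1$cell_line[which.min(g1$gi50)]
resi <- g1$cell_line[which.max(g1$gi50)]
for (line in c(sens, resi)) {
  a <- curves[[paste(line, unique(gt$drug)[1], sep = "|")]]
  b <- curves[[paste(line, unique(gt$drug)[2], sep = "|")]]
  # redundant-target model: the combination acts like the best single agent
  combo <- dose_response_curve(line, "combo", a$doses,
                               pmin(a$reps, b$reps), a$baseline, a$control)
  ce <- combination_effect(list(a, b), combo, n_boot = 500, rng_seed = 1)
  cat(sprintf("%s line %s: combination verdict — %s\n",
              ifelse(line == sens, "sensitive", "resistant"), line, ce$verdict))
}

wells <- read.delim(file.path(data_dir, "sirna_wells.tsv"))
ctrl <- read.delim(file.path(data_dir, "sirna_control_wells.tsv"))$control
mrna <- read.delim(file.path(data_dir, "sirna_mrna.tsv"))
ss <- sirna_screen_stats(wells, ctrl, mrna)
write.table(ss$per_sirna, file.path(out, "sirna_per_sirna.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ss$per_gene, file.path(out, "sirna_per_gene.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("siRNA screen: %d genes called growth-inhibitory (both siRNAs p < 0.05); %d/%d genes with > 50%% knockdown.\n",
            sum(ss$per_gene$call),
            sum(tapply(ss$per_sirna$knockdown, ss$per_sirna$gene, mean) > 0.5),
            length(unique(ss$per_sirna$gene))))
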