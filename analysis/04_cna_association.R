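#!/usr/bin/env Rscript
# Merge copy-number probes into regions, call gain/loss/amp states, scan
# every (conserved gene, region) pair with one-way ANOVA, tier the
# p-values, and order samples by MNAI for the co-amplification view.

suppressPackageStartupMessages(library(mitonet))

data_dir <- "results/data"
out <- "results"

seg <- read_seg(file.path(data_dir, "copy_number_3.seg"))
regions <- merge_regions(seg$values, seg$probe_info, max_dissimilarity = 0.2)
cat("Merged", nrow(seg$values), "copy-number probes into",
    nrow(regions$regions), "regions.\n")

states <- call_states(regions$signal)
signature <- read.delim(file.path(out, "conserved_genes.tsv"))$gene
ds3 <- read_expression(file.path(data_dir, "expression_3.tsv"),
                       file.path(data_dir, "probes_3.tsv"), "cohort_3")
collapsed <- collapse_probes(ds3, signature)$values

assoc <- association_scan(collapsed, states)
write.table(data.frame(gene = rownames(assoc$p), assoc$p, check.names = FALSE),
            file.path(out, "association_p.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(assoc$tier), assoc$tier,
                       check.names = FALSE),
            file.path(out, "association_tier.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tested <- assoc$p[, !assoc$untested, drop = FALSE]
cat(sprintf("Tested %d regions; %.1f%% of (gene, region) pairs significant at p < 1e-7.\n",
            sum(!assoc$untested), 100 * mean(tested < 1e-7, na.rm = TRUE)))

# regions overlapping the planted amplicons show the strongest association
mn <- read.delim(file.path(out, "mnai_3.tsv"))
per_region_min_p <- apply(assoc$p[, !assoc$untested, drop = FALSE], 2,
                          min, na.rm = TRUE)
top <- names(sort(per_region_min_p))[1:min(6, length(per_region_min_p))]
cat("Regions with strongest module association:",
    paste(sprintf("%s (min p = %.1e)", top, per_region_min_p[top]),
          collapse = ", "), "\n")

co <- coamplification_order(states[top, , drop = FALSE], mn)
write.table(data.frame(sample_id = co$sample_order, amp_count = co$amp_count),
            file.path(out, "coamplification_order.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
rho <- cor(mn$mnai[match(co$sample_order, mn$sample_id)], co$amp_count,
           method = "spearman")
cat(sprintf("Spearman correlation between MNAI and driver amp count: %.2f\n", rho))
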