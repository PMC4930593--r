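#!/usr/bin/env Rscript
# Extract promoter windows (-3 kb / +1 kb around the TSS) from the genome
# contigs and scan them with the four TF matrices (MYC, ZEB1, FOXM1, SOX9)
# at Match thresholds core = 1, matrix = 0.85; compare recovered hits with
# the planted site positions.

suppressPackageStartupMessages(library(mitonet))

data_dir <- "results/data"
out <- "results"

genome <- read_fasta(file.path(data_dir, "genome.fasta"))
tss <- read_tss_bed(file.path(data_dir, "tss.bed"))
pwms <- read_pwms(file.path(data_dir, "pwms.txt"))

ex <- extract_promoters(genome, tss)
cat("Extracted", length(ex$promoters), "promoter windows (",
    sum(ex$flags$truncated), "truncated ).\n")

scan <- scan_promoters(pwms, ex$promoters, css_threshold = 1,
                       mss_threshold = 0.85)
write.table(scan$hits, file.path(out, "motif_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(scan$edges, file.path(out, "motif_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

planted <- read.delim(file.path(data_dir, "planted_motifs.tsv"))
hit_key <- paste(scan$hits$gene, scan$hits$pwm, scan$hits$offset,
                 scan$hits$strand)
rec <- mean(paste(planted$gene, planted$pwm, planted$pos, "+") %in% hit_key)
cat(sprintf("%d hits over %d (TF, gene) edges; planted-site recovery %.0f%%.\n",
            nrow(scan$hits), nrow(scan$edges), 100 * rec))

signature <- read.delim(file.path(out, "conserved_genes.tsv"))$gene
per_tf <- table(scan$edges$tf[scan$edges$gene %in% signature])
cat("Conserved network genes with predicted sites per TF:\n")
print(per_tf)
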