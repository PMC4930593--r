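#!/usr/bin/env Rscript
# Generate the three synthetic cohorts with the planted mitotic module and
# write every data layer (expression + probe annotation, copy number,
# survival, dose-response plates, promoters/PWMs, siRNA screen) under
# results/data/. Later scripts read these files, so the whole analysis can
# be reproduced from flat text.

suppressPackageStartupMessages(library(mitonet))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config() # default study conditions; seed 20160701
gen <- generate_expression(cfg)

for (d in seq_along(gen$datasets)) {
  write_expression(gen$datasets[[d]],
                   file.path(out, sprintf("expression_%d.tsv", d)),
                   file.path(out, sprintf("probes_%d.tsv", d)))
  si <- gen$datasets[[d]]$sample_info
  surv <- generate_survival(cfg, gen$truth$activity[[d]],
                            seed = sub_seed(cfg$seed, 200 + d))
  surv$subtype <- si$subtype[match(surv$sample_id, si$sample_id)]
  write_survival(surv, file.path(out, sprintf("survival_%d.csv", d)))
}

cna <- generate_cna(cfg, gen$truth, dataset = 3)
write_seg(cna$values, cna$probe_info, file.path(out, "copy_number_3.seg"))

dr <- generate_dose_response(cfg, gen$truth$activity[[1]],
                             seed = sub_seed(cfg$seed, 400))
write_plates(dr$plates, file.path(out, "plates.csv"))

prom <- generate_promoters(cfg, gen$truth, seed = sub_seed(cfg$seed, 300))
write_fasta(prom$genome, file.path(out, "genome.fasta"))
write_tss_bed(prom$tss, file.path(out, "tss.bed"))
write_pwms(prom$pwms, file.path(out, "pwms.txt"))
write.table(prom$planted, file.path(out, "planted_motifs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

screen <- generate_sirna_screen(cfg, gen$truth, seed = sub_seed(cfg$seed, 500))
write.table(screen$wells, file.path(out, "sirna_wells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(control = screen$control_wells),
            file.path(out, "sirna_control_wells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(screen$mrna, file.path(out, "sirna_mrna.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write.table(data.frame(gene = gen$truth$module_genes),
            file.path(out, "true_module_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", length(gen$datasets), "cohorts (",
    paste(cfg$n_samples, collapse = "/"), "samples ) with a",
    cfg$module_size, "gene module driven by",
    cfg$n_driver_regions, "amplicon regions.\n")
cat("Data written under", out, "\n")
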