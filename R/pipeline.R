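# End-to-end pipeline driver reproducing the analysis order on synthetic
# (or user-supplied) data: network -> conservation -> MNAI -> subtype &
# survival -> CNA scan -> motifs -> pharmacology; writes all outputs and a
# deterministic run manifest.

#' Pipeline configuration
#'
#' @param synthetic a [synthetic_config()] used to generate the cohorts
#'   (user-supplied data can be substituted by passing `datasets`).
#' @param datasets optional list of `expression_dataset` to analyse instead
#'   of generating synthetic cohorts (then CNA/motif/pharmacology stages
#'   that need planted truth are skipped unless inputs are given).
#' @param seeds seed gene symbols.
#' @param n_perm permutations for the null threshold.
#' @param alpha tail probability for the permutation threshold.
#' @param cna_thresholds state-call thresholds c(loss, gain, amp).
#' @param css_threshold,mss_threshold motif-scan thresholds.
#' @param max_dissimilarity region-merge tolerance.
#' @param out_dir output directory.
#' @param rng_seed master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            datasets = NULL,
                            seeds = SEED_GENES,
                            n_perm = 1000, alpha = 2.5e-5,
                            cna_thresholds = c(loss = -0.3, gain = 0.3, amp = 0.8),
                            css_threshold = 1.0, mss_threshold = 0.85,
                            max_dissimilarity = 0.2,
                            out_dir = "mitonet_run",
                            rng_seed = 20160701) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  structure(list(synthetic = synthetic, datasets = datasets, seeds = seeds,
                 n_perm = n_perm, alpha = alpha,
                 cna_thresholds = cna_thresholds,
                 css_threshold = css_threshold, mss_threshold = mss_threshold,
                 max_dissimilarity = max_dissimilarity,
                 out_dir = out_dir, rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()] and
#' [synthetic_config()] (under a `synthetic:` block).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, if (is.null(y$synthetic)) list() else y$synthetic)
  args <- y[setdiff(names(y), "synthetic")]
  do.call(pipeline_config, c(list(synthetic = syn), args))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Deterministic given the configuration: every stage derives its RNG
#' stream from `rng_seed`. Writes the discovery network (SIF/GraphML), the
#' conserved gene list, per-dataset MNAI tables, survival reports, the CNA
#' association matrix and tier map, the motif edge table, the GI50 table
#' with group comparisons, siRNA screen calls, and a JSON run manifest
#' recording seeds, thresholds, stage record counts and deviations.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a result bundle list; files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("mitonet")),
    rng_seed = config$rng_seed,
    n_perm = config$n_perm, alpha = config$alpha,
    seeds = config$seeds,
    deviations = c(
      "region merging: greedy adjacent-probe profile merge (not CGHregions)",
      "conservation rule: per-dataset connectivity at the permutation threshold",
      "Cox covariates entered linearly (no spline terms)",
      "GI50: interpolation of Hill-linearized growth percent vs log10 dose"
    ),
    stages = list()
  )
  stage <- function(name, counts) manifest$stages[[name]] <<- counts

  # --- data ---------------------------------------------------------------
  if (is.null(config$datasets)) {
    syn <- config$synthetic
    syn$seed <- config$rng_seed
    gen <- generate_expression(syn)
    datasets <- gen$datasets
    truth <- gen$truth
  } else {
    datasets <- config$datasets
    truth <- NULL
    syn <- config$synthetic
  }
  for (d in seq_along(datasets)) {
    write_expression(datasets[[d]],
                     file.path(out, sprintf("expression_%d.tsv", d)),
                     file.path(out, sprintf("probes_%d.tsv", d)))
  }
  stage("data", list(n_datasets = length(datasets),
                     n_samples = vapply(datasets, function(d) ncol(d$values), 0L)))

  # --- network discovery + conservation ------------------------------------
  thresholds <- numeric(length(datasets))
  for (d in seq_along(datasets)) {
    thresholds[d] <- permutation_null_threshold(
      datasets[[d]], config$seeds, n_perm = config$n_perm,
      alpha = config$alpha, rng_seed = sub_seed(config$rng_seed, 100 + d)
    )$threshold_r
  }
  discovery <- build_relevance_network(datasets[[1]], config$seeds, thresholds[1])
  write_network(discovery, file.path(out, "network_discovery.sif"),
                file.path(out, "network_discovery.graphml"))
  conserved <- conserve_across_datasets(datasets, discovery$nodes, thresholds)
  write_tsv(data.frame(gene = conserved$gene_ids), file.path(out, "conserved_genes.tsv"))
  manifest$thresholds <- thresholds
  stage("network", list(discovery_nodes = length(discovery$nodes),
                        discovery_edges = nrow(discovery$edges),
                        conserved_genes = length(conserved$gene_ids)))

  # --- MNAI + subtype + survival -------------------------------------------
  signature <- conserved$gene_ids
  mnai_list <- list()
  survival_report <- list()
  for (d in seq_along(datasets)) {
    collapsed <- collapse_probes(datasets[[d]], signature)$values
    mn <- compute_mnai(collapsed, signature, datasets[[d]]$dataset_id)
    mnai_list[[d]] <- mn
    write_tsv(mn, file.path(out, sprintf("mnai_%d.tsv", d)))
    si <- datasets[[d]]$sample_info
    anova_p <- if ("subtype" %in% names(si) && length(unique(si$subtype)) > 1) {
      subtype_anova(mn$mnai[match(si$sample_id, mn$sample_id)], si$subtype)$p
    } else NA_real_
    surv_tab <- if (!is.null(truth)) {
      generate_survival(syn, truth$activity[[d]],
                        seed = sub_seed(config$rng_seed, 200 + d))
    } else if (all(c("time", "event") %in% names(si))) {
      data.frame(sample_id = si$sample_id, time = si$time, event = si$event)
    } else NULL
    if (!is.null(surv_tab)) {
      ts <- tertile_survival(surv_tab, mn)
      cox_tab <- merge(surv_tab, mn[, c("sample_id", "mnai")], by = "sample_id")
      cox_tab$mnai_z <- scale_vec(cox_tab$mnai)
      cx <- cox_fit(cox_tab, "mnai_z")
      survival_report[[d]] <- data.frame(
        dataset = datasets[[d]]$dataset_id,
        logrank_chisq = ts$logrank$chisq, logrank_p = ts$logrank$p,
        cox_mnai_z_coef = cx$coef[1], cox_mnai_z_p = cx$p[1],
        subtype_anova_p = anova_p, stringsAsFactors = FALSE)
    }
  }
  if (length(survival_report)) {
    write_tsv(do.call(rbind, survival_report), file.path(out, "survival_report.tsv"))
  }
  stage("mnai", list(signature_size = length(signature)))

  results <- list(datasets = datasets, truth = truth, thresholds = thresholds,
                  discovery = discovery, conserved = conserved,
                  mnai = mnai_list,
                  survival = if (length(survival_report))
                    do.call(rbind, survival_report) else NULL)

  if (!is.null(truth)) {
    # --- CNA association scan (largest cohort) -----------------------------
    d_big <- which.max(vapply(datasets, function(d) ncol(d$values), 0L))
    cna <- generate_cna(syn, truth, dataset = d_big)
    write_seg(cna$values, cna$probe_info, file.path(out, "copy_number.seg"))
    regions <- merge_regions(cna$values, cna$probe_info,
                             max_dissimilarity = config$max_dissimilarity)
    states <- call_states(regions$signal, config$cna_thresholds)
    expr_big <- collapse_probes(datasets[[d_big]], signature)$values
    assoc <- association_scan(expr_big, states)
    write_tsv(data.frame(gene = rownames(assoc$p), assoc$p, check.names = FALSE),
              file.path(out, "association_p.tsv"))
    write_tsv(data.frame(gene = rownames(assoc$tier), assoc$tier, check.names = FALSE),
              file.path(out, "association_tier.tsv"))
    coamp <- coamplification_order(
      states[rownames(states) %in% region_ids_for_drivers(regions, truth), ,
             drop = FALSE],
      mnai_list[[d_big]])
    write_tsv(data.frame(sample_id = coamp$sample_order,
                         amp_count = coamp$amp_count),
              file.path(out, "coamplification_order.tsv"))
    stage("cna", list(n_regions = nrow(regions$regions),
                      n_tested = sum(!assoc$untested)))
    results$cna <- list(regions = regions, states = states, assoc = assoc,
                        coamp = coamp)

    # --- motif scan ---------------------------------------------------------
    prom <- generate_promoters(syn, truth, seed = sub_seed(config$rng_seed, 300))
    write_fasta(prom$promoters, file.path(out, "promoters.fasta"))
    write_tss_bed(prom$tss, file.path(out, "tss.bed"))
    write_pwms(prom$pwms, file.path(out, "pwms.txt"))
    scan <- scan_promoters(prom$pwms, prom$promoters,
                           config$css_threshold, config$mss_threshold)
    write_tsv(scan$edges, file.path(out, "motif_edges.tsv"))
    write_tsv(scan$hits, file.path(out, "motif_hits.tsv"))
    stage("motifs", list(n_hits = nrow(scan$hits), n_edges = nrow(scan$edges)))
    results$motifs <- list(prom = prom, scan = scan)

    # --- pharmacology -------------------------------------------------------
    act <- truth$activity[[1]]
    dr <- generate_dose_response(syn, act, seed = sub_seed(config$rng_seed, 400))
    write_plates(dr$plates, file.path(out, "plates.csv"))
    curves <- curves_from_plates(dr$plates)
    gt <- gi50_table(curves)
    write_tsv(gt, file.path(out, "gi50_table.tsv"))
    tert <- mnai_list[[1]]
    mw <- list()
    for (drug in unique(gt$drug)) {
      sub <- merge(gt[gt$drug == drug, ], tert[, c("sample_id", "tertile")],
                   by.x = "cell_line", by.y = "sample_id")
      sub <- sub[sub$tertile %in% c("high", "low"), ]
      cmp <- compare_response_groups(sub$gi50, as.character(sub$tertile))
      mw[[drug]] <- data.frame(drug = drug, U = cmp$U, p = cmp$p,
                               median_high = unname(cmp$medians["high"]),
                               median_low = unname(cmp$medians["low"]),
                               stringsAsFactors = FALSE)
    }
    write_tsv(do.call(rbind, mw), file.path(out, "gi50_group_comparison.tsv"))
    drug_cor <- correlate_drug_responses(gt)
    write_tsv(drug_cor, file.path(out, "drug_correlations.tsv"))
    screen <- generate_sirna_screen(syn, truth, seed = sub_seed(config$rng_seed, 500))
    ss <- sirna_screen_stats(screen$wells, screen$control_wells, screen$mrna)
    write_tsv(ss$per_sirna, file.path(out, "sirna_per_sirna.tsv"))
    write_tsv(ss$per_gene, file.path(out, "sirna_per_gene.tsv"))
    stage("pharmacology", list(n_curves = length(curves),
                               n_sirna = nrow(ss$per_sirna),
                               n_gene_calls = sum(ss$per_gene$call)))
    results$pharm <- list(gi50 = gt, group_comparison = do.call(rbind, mw),
                          drug_cor = drug_cor, sirna = ss)
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

# Region ids overlapping the true driver regions (for co-amp display).
region_ids_for_drivers <- function(region_set, truth) {
  dr <- truth$driver_regions
  hits <- character(0)
  for (r in seq_len(nrow(dr))) {
    ov <- region_set$regions$chrom == dr$chrom[r] &
      region_set$regions$start <= dr$end_mb[r] * 1e6 &
      region_set$regions$end >= dr$start_mb[r] * 1e6 + 1
    hits <- c(hits, region_set$regions$region_id[ov])
  }
  unique(hits)
}
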