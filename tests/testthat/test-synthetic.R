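test_that("generator is deterministic and validates its config", {
  cfg <- tiny_config()
  g1 <- generate_expression(cfg)
  g2 <- generate_expression(cfg)
  expect_identical(g1$datasets[[1]]$values, g2$datasets[[1]]$values)
  expect_identical(g1$truth$amp, g2$truth$amp)

  expect_error(synthetic_config(n_genes = 50, module_size = 54), "module_size")
  expect_error(synthetic_config(amp_prob = 1.5), "amp_prob")
  expect_error(synthetic_config(noise_sd = 0), "SD")
})

test_that("planted module genes are more correlated than background", {
  cfg <- synthetic_config(n_samples = 200, n_genes = 300, module_size = 30,
                          seed = 7)
  gen <- generate_expression(cfg)
  ds <- gen$datasets[[1]]
  collapsed <- collapse_probes(ds, gen$truth$gene_ids)$values
  mod <- intersect(gen$truth$module_genes, rownames(collapsed))
  bg <- setdiff(rownames(collapsed), mod)[1:30]
  mean_abs_r <- function(genes) {
    R <- abs(cor(t(collapsed[genes, ])))
    mean(R[upper.tri(R)])
  }
  expect_gt(mean_abs_r(mod), mean_abs_r(bg))
})

test_that("without planted signal, module genes decouple from the seeds", {
  cfg <- synthetic_config(n_samples = 500, n_genes = 100, module_size = 10,
                          beta_amp = 0, module_factor_sd = 1e-9, seed = 11)
  gen <- generate_expression(cfg)
  sc <- suppressWarnings(compute_seed_correlations(gen$datasets[[1]]))
  mod_probes <- gen$datasets[[1]]$probe_info$probe_id[
    gen$datasets[[1]]$probe_info$gene %in% setdiff(gen$truth$module_genes, SEED_GENES)]
  r_mod <- sc$r[sc$probe %in% mod_probes]
  expect_lt(mean(abs(r_mod)), 0.1)
})

test_that("copy-number layer reuses the expression amplicon indicators", {
  cfg <- tiny_config()
  gen <- generate_expression(cfg)
  cna <- generate_cna(cfg, gen$truth, dataset = 1)
  expect_identical(cna$amp, gen$truth$amp[[1]])
  # amplified driver probes are shifted by ~1, neutral ones near 0
  dr <- gen$truth$driver_regions$region_id[1]
  probes <- cna$probe_info$probe_id[cna$probe_info$region_truth %in% dr]
  amp_s <- cna$amp[dr, ] == 1
  expect_gt(mean(cna$values[probes, amp_s]), 0.8)
  expect_lt(abs(mean(cna$values[probes, !amp_s])), 0.1)
})

test_that("amplification frequency matches amp_prob within binomial bounds", {
  cfg <- synthetic_config(n_samples = 400, n_genes = 60, module_size = 10,
                          amp_prob = 0.25, seed = 13)
  gen <- generate_expression(cfg)
  A <- gen$truth$amp[[1]]
  frac <- rowMeans(A)
  ci_half <- 2.58 * sqrt(0.25 * 0.75 / ncol(A))
  expect_true(all(abs(frac - 0.25) <= ci_half))

  a0 <- generate_expression(synthetic_config(n_samples = 30, n_genes = 60,
                                             module_size = 10, amp_prob = 0,
                                             seed = 13))$truth$amp[[1]]
  expect_true(all(a0 == 0))
  a1 <- generate_expression(synthetic_config(n_samples = 30, n_genes = 60,
                                             module_size = 10, amp_prob = 1,
                                             seed = 13))$truth$amp[[1]]
  expect_true(all(a1 == 1))
})

test_that("probe annotation honours the bad-only exception genes", {
  cfg <- synthetic_config(seed = 3)
  pi <- generate_expression(cfg)$datasets[[1]]$probe_info
  for (g in c("DEPDC1", "GTSE1")) {
    expect_identical(pi$quality[pi$gene == g], "bad")
  }
  # every other gene has at least one perfect/good probe
  other <- setdiff(unique(pi$gene), c("DEPDC1", "GTSE1"))
  has_good <- tapply(pi$quality %in% c("perfect", "good"), pi$gene, any)
  expect_true(all(has_good[other]))
})

test_that("survival generator couples hazard to activity and censors ~30%", {
  cfg <- synthetic_config(n_samples = 2000, n_genes = 60, module_size = 10,
                          seed = 5)
  act <- rnorm(2000)
  names(act) <- paste0("s", 1:2000)
  surv <- generate_survival(cfg, act, seed = 99)
  expect_equal(1 - mean(surv$event), 0.3, tolerance = 0.15)
  # higher activity -> shorter event times
  ev <- surv$event == 1
  expect_lt(cor(act[ev], surv$time[ev], method = "spearman"), -0.2)
  expect_error(generate_survival(cfg, c(1, NA, 2)), "non-finite")

  # no censoring window -> all events
  cfg0 <- synthetic_config(censor_max = 1e9, seed = 5)
  expect_true(all(generate_survival(cfg0, act, seed = 99)$event == 1))
})

test_that("dose grid is nine exact 1:5 dilutions from 30 uM", {
  d <- dose_grid()
  expect_length(d, 9)
  expect_equal(d[1], 30000)
  expect_equal(d[-9] / d[-1], rep(5, 8))
})

test_that("dose-response truth shifts GI50 with activity", {
  cfg <- synthetic_config(seed = 21)
  act <- setNames(c(rep(-1, 25), rep(1, 25)), paste0("c", 1:50))
  dr <- generate_dose_response(cfg, act, drugs = "drugA", seed = 8)
  hi <- dr$truth$log10_gi50[dr$truth$cell_line %in% paste0("c", 26:50)]
  lo <- dr$truth$log10_gi50[dr$truth$cell_line %in% paste0("c", 1:25)]
  expect_lt(mean(hi), mean(lo)) # negative slope: active lines more sensitive
})

test_that("promoter generator plants recoverable consensus sites", {
  cfg <- tiny_config()
  gen <- generate_expression(cfg)
  prom <- generate_promoters(cfg, gen$truth, seed = 4)
  expect_true(all(nchar(prom$promoters) == 4001))
  pl <- prom$planted
  expect_true(all(pl$gene %in% gen$truth$module_genes))
  # planted positions carry the exact consensus
  for (i in sample(nrow(pl), 20)) {
    cons <- mitonet:::pwm_consensus(prom$pwms[[pl$pwm[i]]]$counts)
    expect_identical(substr(prom$promoters[[pl$gene[i]]], pl$pos[i],
                            pl$pos[i] + nchar(cons) - 1), cons)
  }
  # plant rate 0 leaves promoters motif-free at the planted-position level
  prom0 <- generate_promoters(cfg, gen$truth, plant_rate = 0, seed = 4)
  expect_identical(nrow(prom0$planted), 0L)
})
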