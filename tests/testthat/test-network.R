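test_that("seed correlations match hand-evaluated Pearson values", {
  vals <- rbind(
    PLK1 = c(1, 2, 3, 4),
    g2 = c(1, 3, 2, 4),
    g3 = c(1, 2, 3, 4),
    g4 = c(5, 5, 5, 5)
  )
  ds <- toy_dataset(vals)
  sc <- suppressWarnings(compute_seed_correlations(ds, seeds = "PLK1"))
  expect_equal(sc$r[sc$probe == "g2"], 0.8) # cov 4 over sqrt(5 * 5)
  expect_equal(sc$r[sc$probe == "g3"], 1.0)
  expect_false("g4" %in% sc$probe) # constant probe excluded, not r = 0
  excl <- attr(sc, "excluded")
  expect_identical(excl$reason[excl$probe_id == "g4"], "zero variance")
  expect_error(compute_seed_correlations(ds, seeds = "ABSENT"), "ABSENT")
})

test_that("permutation threshold behaves like an empirical null quantile", {
  cfg <- synthetic_config(n_samples = 60, n_genes = 120, module_size = 10,
                          seed = 17)
  ds <- generate_expression(cfg)$datasets[[1]]
  thr_hi <- permutation_null_threshold(ds, n_perm = 50, alpha = 0.001,
                                       rng_seed = 1)
  thr_lo <- permutation_null_threshold(ds, n_perm = 50, alpha = 0.05,
                                       rng_seed = 1)
  expect_gte(thr_hi$threshold_r, thr_lo$threshold_r) # quantile monotonicity
  # alpha -> 1 gives (near) the minimum pooled null |r|
  thr_all <- permutation_null_threshold(ds, n_perm = 20, alpha = 0.999999,
                                        rng_seed = 1)
  expect_lt(thr_all$threshold_r, 0.01)
  expect_error(
    permutation_null_threshold(ds, n_perm = 2, alpha = 1e-9, rng_seed = 1),
    "resolution")
})

test_that("threshold agrees with the analytic Gaussian null quantile", {
  # independent Gaussian profiles: null |r| has a known t-transform quantile
  n <- 50
  n_probes <- 400
  vals <- with_seed(23, matrix(rnorm((n_probes + 3) * n), ncol = n))
  rownames(vals) <- c("PLK1", "CENPE", "AURKB", paste0("g", seq_len(n_probes)))
  ds <- toy_dataset(vals)
  alpha <- 2e-4
  thr <- permutation_null_threshold(ds, n_perm = 200, alpha = alpha,
                                    rng_seed = 3)$threshold_r
  tq <- qt(1 - alpha / 2, df = n - 2) # two tails pooled as |r|
  r_analytic <- tq / sqrt(n - 2 + tq^2)
  expect_equal(thr, r_analytic, tolerance = 0.05)
})

test_that("network edges equal the brute-force all-pairs filter", {
  for (rep in 1:3) {
    vals <- with_seed(100 + rep, {
      base <- matrix(rnorm(10 * 8), nrow = 10)
      base[2, ] <- base[1, ] + rnorm(8, 0, 0.1)
      base[3, ] <- base[1, ] + rnorm(8, 0, 0.2)
      base
    })
    rownames(vals) <- c("PLK1", paste0("g", 2:10))
    ds <- toy_dataset(vals)
    thr <- 0.5
    net <- build_relevance_network(ds, seeds = "PLK1", threshold_r = thr)
    collapsed <- collapse_probes(ds, sort(net$nodes))$values
    oracle <- brute_force_edges(collapsed, thr)
    got <- net$edges[order(net$edges$gene_a, net$edges$gene_b), ]
    want <- oracle[order(oracle$gene_a, oracle$gene_b), ]
    expect_identical(got$gene_a, want$gene_a)
    expect_identical(got$gene_b, want$gene_b)
    expect_equal(got$r, want$r, tolerance = 1e-12)
  }
})

test_that("network node rules: threshold above max, seed inclusion, symmetry", {
  vals <- with_seed(5, matrix(rnorm(6 * 10), nrow = 6))
  rownames(vals) <- c("PLK1", paste0("g", 2:6))
  ds <- toy_dataset(vals)
  net <- build_relevance_network(ds, seeds = "PLK1", threshold_r = 0.9999)
  expect_identical(net$nodes, "PLK1") # seeds retained even with no passers
  expect_identical(nrow(net$edges), 0L)
  # each undirected edge appears exactly once, a < b
  net2 <- build_relevance_network(ds, seeds = "PLK1", threshold_r = 0.1)
  key <- paste(pmin(net2$edges$gene_a, net2$edges$gene_b),
               pmax(net2$edges$gene_a, net2$edges$gene_b))
  expect_false(any(duplicated(key)))
  expect_true(all(net2$edges$gene_a < net2$edges$gene_b))
})

test_that("enlarging the seed set never shrinks the node set", {
  cfg <- synthetic_config(n_samples = 80, n_genes = 150, module_size = 15,
                          seed = 31)
  ds <- generate_expression(cfg)$datasets[[1]]
  n1 <- build_relevance_network(ds, seeds = "PLK1", threshold_r = 0.5)
  n2 <- build_relevance_network(ds, seeds = c("PLK1", "CENPE"), threshold_r = 0.5)
  n3 <- build_relevance_network(ds, seeds = SEED_GENES, threshold_r = 0.5)
  expect_true(all(n1$nodes %in% n2$nodes))
  expect_true(all(n2$nodes %in% n3$nodes))
})

test_that("conservation keeps connected genes and reports drop reasons", {
  # dataset A: g1,g2 correlated; dataset B misses g3 entirely
  mk <- function(id, genes, corr_pair) {
    vals <- with_seed(7, matrix(rnorm(length(genes) * 20), nrow = length(genes)))
    rownames(vals) <- genes
    vals[corr_pair[2], ] <- vals[corr_pair[1], ] + rnorm(20, 0, 0.05)
    toy_dataset(vals, id = id)
  }
  dsA <- mk("A", c("g1", "g2", "g3"), c("g1", "g2"))
  dsB <- mk("B", c("g1", "g2"), c("g1", "g2"))
  cons <- conserve_across_datasets(list(dsA, dsB), c("g1", "g2", "g3"),
                                   thresholds = 0.9)
  expect_setequal(cons$gene_ids, c("g1", "g2"))
  drop_g3 <- cons$dropped[cons$dropped$gene == "g3", ]
  expect_setequal(drop_g3$reason, c("disconnected", "absent"))

  # single-dataset input: connectivity rule applied to the candidate set
  cons1 <- conserve_across_datasets(list(dsA), c("g1", "g2", "g3"), 0.9)
  expect_setequal(cons1$gene_ids, c("g1", "g2"))
})

test_that("whole-dataset sample permutation leaves the threshold unchanged", {
  cfg <- synthetic_config(n_samples = 40, n_genes = 100, module_size = 10,
                          seed = 19)
  ds <- generate_expression(cfg)$datasets[[1]]
  perm <- with_seed(77, sample.int(ncol(ds$values)))
  ds_perm <- expression_dataset(ds$values[, perm],
                                ds$probe_info,
                                ds$sample_info[perm, , drop = FALSE],
                                dataset_id = "perm")
  t1 <- permutation_null_threshold(ds, n_perm = 100, alpha = 0.01, rng_seed = 9)
  t2 <- permutation_null_threshold(ds_perm, n_perm = 100, alpha = 0.01, rng_seed = 9)
  expect_equal(t1$threshold_r, t2$threshold_r, tolerance = 0.03)
})
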