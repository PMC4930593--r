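test_that("growth percent follows the NCI definition and is scale-invariant", {
  expect_equal(growth_percent(200, 100, 200), 100) # T = C
  expect_equal(growth_percent(100, 100, 200), 0)   # T = T0
  expect_equal(growth_percent(150, 100, 200), 50)
  expect_equal(growth_percent(50, 100, 200), -50)  # lethality scale
  for (k in c(0.5, 3, 100)) {
    expect_equal(growth_percent(150 * k, 100 * k, 200 * k), 50)
    expect_equal(growth_percent(60 * k, 100 * k, 200 * k),
                 growth_percent(60, 100, 200))
  }
  expect_true(is.na(growth_percent(150, 100, 100))) # C == T0 undefined
})

mk_curve <- function(gp, doses = dose_grid()) {
  # wells engineered so mean growth percent equals gp exactly
  T0 <- 100; C <- 300
  T_sig <- T0 + (C - T0) * gp / 100
  dose_response_curve("cl", "drug", doses, cbind(T_sig, T_sig, T_sig), T0, C)
}

test_that("GI50 interpolation matches hand values and analytic Hill inversion", {
  # growth 60 at 1 nM and 40 at 10 nM -> crossing at 10^0.5 (symmetric point)
  cv <- mk_curve(c(40, 60), doses = c(10, 1))
  est <- estimate_gi50(cv)
  expect_equal(est$gi50, 10^0.5, tolerance = 1e-9)
  est_lin <- estimate_gi50(cv, method = "linear")
  expect_equal(est_lin$gi50, 10^0.5, tolerance = 1e-9)

  # noiseless Hill slope-1 curves: recovery within interpolation tolerance
  for (g_true in c(3.7, 55, 410, 2600)) {
    gp <- 100 / (1 + dose_grid() / g_true)
    est <- estimate_gi50(mk_curve(gp))
    expect_equal(est$gi50, g_true, tolerance = 0.02)
    expect_identical(est$gi50_flag, "in_range")
  }

  # 4PL fit mode agrees on a clean curve
  if (requireNamespace("minpack.lm", quietly = TRUE)) {
    est_4pl <- estimate_gi50(mk_curve(100 / (1 + dose_grid() / 410)),
                             method = "4pl")
    expect_equal(est_4pl$gi50, 410, tolerance = 0.02)
  }

  # curve never below 50 -> reported at the top dose with a flag
  high <- estimate_gi50(mk_curve(rep(80, 9)))
  expect_equal(high$gi50, 30000)
  expect_identical(high$gi50_flag, "above_range")
  low <- estimate_gi50(mk_curve(rep(20, 9)))
  expect_identical(low$gi50_flag, "below_range")

  # TGI: crossing of zero on a lethal curve
  gp <- seq(-40, 80, length.out = 9) # top dose first: lethal at high dose
  tgi <- estimate_gi50(mk_curve(gp))
  expect_identical(tgi$tgi_flag, "in_range")
  expect_true(tgi$tgi > min(dose_grid()) && tgi$tgi < max(dose_grid()))
})

test_that("GI50 is monotone under uniform downward shifts", {
  gp <- 100 / (1 + dose_grid() / 200)
  g_base <- estimate_gi50(mk_curve(gp))$gi50
  g_down <- estimate_gi50(mk_curve(gp - 15))$gi50
  expect_lte(g_down, g_base)
})

test_that("Mann-Whitney comparison: exact enumeration and invariances", {
  # identical samples -> p = 1
  same <- compare_response_groups(c(1, 2, 3, 1, 2, 3),
                                  rep(c("high", "low"), each = 3))
  expect_equal(same$p, 1)
  # (1,2,3) vs (4,5,6): U = 0, exact two-sided p = 2/20
  sep <- compare_response_groups(c(1, 2, 3, 4, 5, 6),
                                 rep(c("high", "low"), each = 3))
  expect_equal(unname(sep$U), 0)
  expect_equal(sep$p, 0.1)
  # invariance under strictly monotone transforms
  x <- with_seed(9, rlnorm(20))
  g <- rep(c("high", "low"), 10)
  expect_equal(compare_response_groups(x, g)$p,
               compare_response_groups(log10(x), g)$p)
  expect_error(compare_response_groups(x[1:10], rep("high", 10)), "two groups")
})

test_that("drug response correlations behave as Pearson on log10 GI50", {
  tab <- data.frame(cell_line = rep(paste0("c", 1:5), 2),
                    drug = rep(c("A", "B"), each = 5),
                    gi50 = c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50))
  cors <- correlate_drug_responses(tab)
  expect_equal(cors$r, 1, tolerance = 1e-12) # same log-profile
  tab$gi50[6:10] <- 10 / tab$gi50[1:5] # log10 B = 1 - log10 A
  expect_equal(correlate_drug_responses(tab)$r, -1, tolerance = 1e-12)
  # pairs with < 3 shared lines are skipped
  tab2 <- tab[c(1:5, 6:7), ]
  expect_identical(nrow(correlate_drug_responses(tab2)), 0L)
})

test_that("synthetic drugs sharing the activity-linked GI50 are correlated", {
  cfg <- synthetic_config(seed = 55)
  act <- with_seed(56, setNames(rnorm(50), paste0("c", 1:50)))
  dr <- generate_dose_response(cfg, act, seed = 57)
  gt <- gi50_table(curves_from_plates(dr$plates))
  cors <- correlate_drug_responses(gt)
  expect_identical(nrow(cors), 3L)
  expect_true(all(cors$r > 0.5))
  expect_true(all(cors$p < 0.01))
})

test_that("combination comparison flags redundancy and Bliss synergy", {
  gp_a <- 100 / (1 + dose_grid() / 100)
  gp_b <- 100 / (1 + dose_grid() / 300)
  a <- mk_curve(gp_a); b <- mk_curve(gp_b)
  # combo identical to the best single -> zero differences, no added effect
  combo_same <- mk_curve(pmin(gp_a, gp_b))
  res <- combination_effect(list(a, b), combo_same, n_boot = 200, rng_seed = 1)
  expect_true(all(abs(res$report$diff) < 1e-9))
  expect_identical(res$verdict, "no added effect")
  # Bliss-product combo is more inhibitory where both singles are active
  combo_bliss <- mk_curve(gp_a * gp_b / 100)
  res2 <- combination_effect(list(a, b), combo_bliss, n_boot = 200, rng_seed = 1)
  active <- gp_a < 95 & gp_b < 95
  expect_true(all(res2$report$diff[active] < 0))
  expect_equal(res2$report$bliss_expected, gp_a * gp_b / 100, tolerance = 1e-9)
  # grid mismatch errors
  shifted <- mk_curve(gp_a, doses = dose_grid() / 2)
  expect_error(combination_effect(list(a, b), shifted, n_boot = 10), "grid")
})

test_that("siRNA screen statistics recover planted growth genes", {
  cfg <- tiny_config()
  gen <- generate_expression(cfg)
  screen <- generate_sirna_screen(cfg, gen$truth, n_growth_genes = 8, seed = 2)
  ss <- sirna_screen_stats(screen$wells, screen$control_wells, screen$mrna)
  called <- ss$per_gene$gene[ss$per_gene$call]
  expect_gte(length(intersect(called, screen$growth_genes)),
             length(screen$growth_genes) - 1)
  # wells identical to control -> viability 1, p ~ 1
  ctrl <- rep(1000, 6)
  wells <- data.frame(sirna = "g_si1", gene = "g",
                      rep1 = 1000, rep2 = 1000, rep3 = 1000)
  flat <- suppressWarnings(sirna_screen_stats(wells, ctrl))
  expect_equal(flat$per_sirna$relative_viability, 1)
  # knockdown arithmetic: control ratio 1, siRNA ratio 0.4 -> 0.6
  mr <- data.frame(sirna = "g_si1", gene = "g", ratio = 0.4, control_ratio = 1)
  kd <- suppressWarnings(sirna_screen_stats(wells, ctrl, mr))
  expect_equal(kd$per_sirna$knockdown, 0.6)
  expect_error(sirna_screen_stats(wells, NULL), "control")
})
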