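# NCI-style dose-response processing (growth percent, GI50, TGI),
# high-vs-low MNAI response comparison, inter-drug GI50 correlation,
# pairwise-combination comparison and siRNA screen statistics.

#' NCI growth percent
#'
#' `100 * (T - T0) / (C - T0)` when the treated signal T is at or above the
#' time-0 baseline T0, and `100 * (T - T0) / T0` (lethality scale) when it
#' falls below; C is the untreated 72-h control.
#'
#' @param T treated signal (vectorized).
#' @param T0 time-0 baseline.
#' @param C untreated control signal.
#' @return growth percent; NA where C == T0 (undefined, flag the curve).
#' @export
growth_percent <- function(T, T0, C) {
  out <- ifelse(T >= T0, 100 * (T - T0) / (C - T0), 100 * (T - T0) / T0)
  out[C == T0 & T >= T0] <- NA_real_
  out
}

#' Build a dose-response curve from plate wells
#'
#' @param cell_line,drug identifiers.
#' @param doses dose grid in nM (any order; stored decreasing).
#' @param reps replicate luminescence matrix (doses x replicates) or
#'   data.frame of rep columns.
#' @param baseline time-0 signal T0.
#' @param control untreated 72-h signal C.
#' @return a `dose_response_curve` with per-dose mean growth percent.
#' @export
dose_response_curve <- function(cell_line, drug, doses, reps, baseline, control) {
  reps <- as.matrix(reps)
  stopifnot(nrow(reps) == length(doses), ncol(reps) >= 2)
  ord <- order(-doses)
  doses <- doses[ord]
  reps <- reps[ord, , drop = FALSE]
  flagged_control <- control <= baseline
  gp_reps <- apply(reps, 2, growth_percent, T0 = baseline, C = control)
  gp <- rowMeans(gp_reps, na.rm = TRUE)
  structure(list(cell_line = cell_line, drug = drug, doses = doses,
                 reps = reps, baseline = baseline, control = control,
                 growth_percent = gp, growth_percent_reps = gp_reps,
                 flagged_control = flagged_control),
            class = "dose_response_curve")
}

#' Curves from a long plate table
#' @param plates data.frame as from [read_plates()].
#' @return named list of `dose_response_curve`, one per (cell_line, drug).
#' @export
curves_from_plates <- function(plates) {
  rep_cols <- grep("^rep", names(plates), value = TRUE)
  out <- list()
  for (key in split(seq_len(nrow(plates)),
                    paste(plates$cell_line, plates$drug, sep = "|"))) {
    block <- plates[key, , drop = FALSE]
    cv <- dose_response_curve(block$cell_line[1], block$drug[1], block$dose_nM,
                              block[, rep_cols], block$baseline[1], block$control[1])
    out[[paste(block$cell_line[1], block$drug[1], sep = "|")]] <- cv
  }
  out
}

# Interpolate the log10 dose at which the growth curve crosses `level`.
# method "hill": interpolate the Hill-linearized response (logit of growth
# percent / 100) against log10 dose between the bracketing doses — exact for
# ideal Hill curves; falls back to plain linear interpolation when a
# bracketing value lies outside (0, 100). method "linear": plain linear
# interpolation of growth percent vs log10 dose.
interp_crossing <- function(doses_desc, gp, level, method = "hill") {
  ld <- log10(rev(doses_desc)) # increasing dose
  y <- rev(gp)
  ok <- is.finite(y)
  ld <- ld[ok]; y <- y[ok]
  if (length(y) < 2) return(list(value = NA_real_, flag = "undefined"))
  above <- y > level
  cross <- which(above[-length(y)] & !above[-1])
  if (!length(cross)) {
    if (all(y > level)) {
      return(list(value = max(10^ld), flag = "above_range"))
    }
    return(list(value = min(10^ld), flag = "below_range"))
  }
  i <- cross[1]
  y1 <- y[i]; y2 <- y[i + 1]
  use_hill <- method == "hill" && level > 0 && level < 100 &&
    y1 > 0 && y1 < 100 && y2 > 0 && y2 < 100
  if (use_hill) {
    t1 <- qlogis(y1 / 100); t2 <- qlogis(y2 / 100); tl <- qlogis(level / 100)
  } else {
    t1 <- y1; t2 <- y2; tl <- level
  }
  frac <- (t1 - tl) / (t1 - t2)
  list(value = 10^(ld[i] + frac * (ld[i + 1] - ld[i])), flag = "in_range")
}

#' Estimate GI50 and TGI from a dose-response curve
#'
#' GI50 is the dose at which mean growth percent crosses 50, TGI the
#' crossing of 0. The default interpolates the Hill-linearized growth
#' percent against log10 dose between the bracketing doses (exact on ideal
#' slope-1 curves); `method = "linear"` interpolates growth percent
#' directly, and `method = "4pl"` fits a four-parameter logistic (requires
#' minpack.lm). Curves that never cross return the nearest dose-range bound
#' with an out-of-range flag.
#'
#' @param curve a `dose_response_curve`.
#' @param method "hill", "linear" or "4pl".
#' @return list(gi50, tgi, gi50_flag, tgi_flag) with doses in nM;
#'   gi50_flag/tgi_flag in in_range/above_range/below_range.
#' @export
estimate_gi50 <- function(curve, method = c("hill", "linear", "4pl")) {
  method <- match.arg(method)
  gp <- curve$growth_percent
  if (all(!is.finite(gp))) stop("all growth percents undefined for this curve")
  if (method == "4pl") {
    if (!requireNamespace("minpack.lm", quietly = TRUE)) {
      stop("method '4pl' requires the minpack.lm package")
    }
    df <- data.frame(ld = log10(curve$doses), gp = gp)
    fit <- minpack.lm::nlsLM(
      gp ~ bottom + (top - bottom) / (1 + 10^(h * (ld - e))), data = df,
      start = list(bottom = min(gp), top = max(gp), h = 1,
                   e = stats::median(df$ld)))
    cf <- coef(fit)
    solve_level <- function(level) {
      if ((level - cf["bottom"]) * (cf["top"] - level) <= 0) {
        if (min(gp, na.rm = TRUE) > level) {
          return(list(value = max(curve$doses), flag = "above_range"))
        }
        return(list(value = min(curve$doses), flag = "below_range"))
      }
      ld <- cf["e"] + log10((cf["top"] - level) / (level - cf["bottom"])) / cf["h"]
      lo <- log10(min(curve$doses)); hi <- log10(max(curve$doses))
      if (ld > hi) return(list(value = 10^hi, flag = "above_range"))
      if (ld < lo) return(list(value = 10^lo, flag = "below_range"))
      list(value = unname(10^ld), flag = "in_range")
    }
    g <- solve_level(50); t0 <- solve_level(0)
  } else {
    g <- interp_crossing(curve$doses, gp, 50, method)
    t0 <- interp_crossing(curve$doses, gp, 0, "linear")
  }
  list(gi50 = g$value, tgi = t0$value, gi50_flag = g$flag, tgi_flag = t0$flag)
}

#' GI50 table for a list of curves
#' @param curves list of `dose_response_curve`.
#' @param method passed to [estimate_gi50()].
#' @return data.frame(cell_line, drug, gi50, tgi, gi50_flag, tgi_flag).
#' @export
gi50_table <- function(curves, method = "hill") {
  do.call(rbind, lapply(curves, function(cv) {
    est <- estimate_gi50(cv, method = method)
    data.frame(cell_line = cv$cell_line, drug = cv$drug, gi50 = est$gi50,
               tgi = est$tgi, gi50_flag = est$gi50_flag,
               tgi_flag = est$tgi_flag, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Two-tailed Mann-Whitney U comparison of GI50s between MNAI groups
#'
#' Exact enumeration when both groups have n <= 8 and no ties; otherwise
#' the normal approximation with tie correction.
#'
#' @param gi50s numeric response values.
#' @param groups two-level labels (e.g. high/low MNAI).
#' @return list(U, p, n1, n2, medians).
#' @export
compare_response_groups <- function(gi50s, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups")
  x <- gi50s[groups == lev[1]]
  y <- gi50s[groups == lev[2]]
  if (!length(x) || !length(y)) stop("empty group")
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       n1 = length(x), n2 = length(y),
       medians = setNames(c(median(x), median(y)), lev))
}

#' Pairwise Pearson correlation of log10 GI50 across drugs
#'
#' @param gi50_tab data.frame(cell_line, drug, gi50).
#' @return data.frame(drug_a, drug_b, n, r, p); pairs with fewer than 3
#'   shared cell lines are skipped.
#' @export
correlate_drug_responses <- function(gi50_tab) {
  drugs <- unique(gi50_tab$drug)
  out <- list()
  for (i in seq_along(drugs)) for (j in seq_along(drugs)) {
    if (j <= i) next
    a <- gi50_tab[gi50_tab$drug == drugs[i], c("cell_line", "gi50")]
    b <- gi50_tab[gi50_tab$drug == drugs[j], c("cell_line", "gi50")]
    m <- merge(a, b, by = "cell_line")
    m <- m[is.finite(m$gi50.x) & is.finite(m$gi50.y), ]
    if (nrow(m) < 3) next
    ct <- cor.test(log10(m$gi50.x), log10(m$gi50.y))
    out[[length(out) + 1]] <- data.frame(
      drug_a = drugs[i], drug_b = drugs[j], n = nrow(m),
      r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(drug_a = character(), drug_b = character(),
                      n = integer(), r = numeric(), p = numeric()))
  }
  do.call(rbind, out)
}

#' Compare a drug combination against the best single agent
#'
#' Per dose: combination mean growth percent minus the best (most
#' inhibitory) single-agent mean, with a bootstrap percentile CI over
#' replicate wells. The Bliss-independence expectation is reported as a
#' reference column only. Verdict is "no added effect" when every per-dose
#' CI covers 0.
#'
#' @param singles list of single-agent `dose_response_curve`s.
#' @param combo the combination `dose_response_curve` (same dose grid).
#' @param n_boot bootstrap resamples.
#' @param rng_seed RNG seed for the bootstrap.
#' @return list(report data.frame(dose_nM, gp_combo, gp_best_single, diff,
#'   ci_lo, ci_hi, bliss_expected), verdict).
#' @export
combination_effect <- function(singles, combo, n_boot = 1000, rng_seed = 1) {
  for (s in singles) {
    if (!isTRUE(all.equal(s$doses, combo$doses))) {
      stop("dose grid mismatch between combination and single-agent curves")
    }
  }
  gp_singles <- vapply(singles, function(s) s$growth_percent,
                       numeric(length(combo$doses)))
  best <- apply(gp_singles, 1, min)
  diff_obs <- combo$growth_percent - best
  boot <- with_seed(rng_seed, {
    vapply(seq_len(n_boot), function(b) {
      gp_c <- rowMeans(combo$growth_percent_reps[
        , sample.int(ncol(combo$growth_percent_reps), replace = TRUE),
        drop = FALSE], na.rm = TRUE)
      gp_s <- vapply(singles, function(s) {
        rowMeans(s$growth_percent_reps[
          , sample.int(ncol(s$growth_percent_reps), replace = TRUE),
          drop = FALSE], na.rm = TRUE)
      }, numeric(length(combo$doses)))
      gp_c - apply(gp_s, 1, min)
    }, numeric(length(combo$doses)))
  })
  ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  bliss <- if (length(singles) == 2) {
    a <- pmin(pmax(gp_singles[, 1], 0), 100)
    b <- pmin(pmax(gp_singles[, 2], 0), 100)
    a * b / 100
  } else {
    rep(NA_real_, length(combo$doses))
  }
  report <- data.frame(dose_nM = combo$doses, gp_combo = combo$growth_percent,
                       gp_best_single = best, diff = diff_obs,
                       ci_lo = ci[1, ], ci_hi = ci[2, ],
                       bliss_expected = bliss)
  verdict <- if (all(report$ci_lo <= 0 & report$ci_hi >= 0)) {
    "no added effect"
  } else {
    "added effect at some dose"
  }
  list(report = report, verdict = verdict)
}

#' siRNA growth-screen statistics
#'
#' Per siRNA: relative viability (mean siRNA wells / mean control wells)
#' and a two-sided Welch t-test against the control wells; knockdown
#' fraction from the target/actin ratios normalized to the control siRNA.
#' A gene is called when both of its siRNAs reach p < `alpha` in the same
#' direction.
#'
#' @param wells data.frame(sirna, gene, rep1..repK).
#' @param control_wells numeric control-siRNA well values (>= 2).
#' @param mrna data.frame(sirna, ratio, control_ratio) of target/actin
#'   ratios (optional; NULL skips knockdown reporting).
#' @param alpha per-siRNA significance level.
#' @return list(per_sirna data.frame(sirna, gene, relative_viability, p,
#'   knockdown), per_gene data.frame(gene, call, direction)).
#' @export
sirna_screen_stats <- function(wells, control_wells, mrna = NULL, alpha = 0.05) {
  if (is.null(control_wells) || length(control_wells) < 2) {
    stop("control wells missing (need >= 2)")
  }
  rep_cols <- grep("^rep", names(wells), value = TRUE)
  stopifnot(length(rep_cols) >= 2)
  ctrl_mean <- mean(control_wells)
  per <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    w <- as.numeric(wells[i, rep_cols])
    # degenerate (constant) data: p = 1 when means agree, else 0
    p_val <- tryCatch(t.test(w, control_wells)$p.value,
                      error = function(e) {
                        if (isTRUE(all.equal(mean(w), ctrl_mean))) 1 else 0
                      })
    kd <- NA_real_
    if (!is.null(mrna)) {
      row <- mrna[mrna$sirna == wells$sirna[i], ]
      if (nrow(row)) kd <- 1 - row$ratio[1] / row$control_ratio[1]
    }
    data.frame(sirna = wells$sirna[i], gene = wells$gene[i],
               relative_viability = mean(w) / ctrl_mean, p = p_val,
               knockdown = kd, stringsAsFactors = FALSE)
  }))
  per_gene <- do.call(rbind, lapply(split(per, per$gene), function(d) {
    sig <- d$p < alpha
    dir <- sign(d$relative_viability - 1)
    call <- nrow(d) >= 2 && all(sig) && length(unique(dir)) == 1
    data.frame(gene = d$gene[1], call = call,
               direction = if (call) c("-1" = "inhibits", "0" = "none",
                                       "1" = "promotes")[as.character(dir[1])]
               else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  list(per_sirna = per, per_gene = per_gene)
}
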