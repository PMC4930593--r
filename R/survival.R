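# Kaplan-Meier estimation, two-group log-rank comparison of MNAI tertiles,
# and covariate-adjusted Cox proportional-hazards fits, via the survival
# package (Breslow tie handling).

validate_survival_table <- function(table) {
  need <- c("time", "event")
  stopifnot(all(need %in% names(table)))
  bad <- which(!(table$time > 0) | !is.finite(table$time))
  if (length(bad)) {
    warning("rejecting ", length(bad), " row(s) with nonpositive or non-finite time")
    table <- table[-bad, , drop = FALSE]
  }
  stopifnot(all(table$event %in% c(0, 1)))
  table
}

#' Kaplan-Meier product-limit estimate
#'
#' @param table data.frame with time (> 0) and event (1 = event,
#'   0 = censored); rows with nonpositive time are rejected with a warning.
#' @return data.frame(time, n_risk, n_event, n_censor, surv), one row per
#'   observed time; S(0) = 1 implicitly.
#' @export
km_estimate <- function(table) {
  table <- validate_survival_table(table)
  stopifnot(nrow(table) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param table survival table.
#' @param group two-level group labels aligned with `table` rows.
#' @return list(chisq, p (1 df), observed, expected, n).
#' @export
logrank_test <- function(table, group) {
  stopifnot(length(group) == nrow(table))
  table$..group <- as.character(group)
  table <- validate_survival_table(table)
  counts <- table(table$..group)
  if (length(counts) != 2 || any(counts == 0)) {
    stop("log-rank comparison requires exactly two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ ..group, data = table)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp, n = sd$n)
}

#' Cox proportional-hazards fit with Breslow tie handling
#'
#' Constant covariates are dropped with a warning; categorical covariates
#' are handled by the usual treatment contrasts.
#'
#' @param table survival table containing the covariate columns.
#' @param covariates character vector of covariate column names.
#' @return data.frame(term, coef, hr, se, z, p); the fitted model is
#'   attached as attribute `fit`.
#' @export
cox_fit <- function(table, covariates) {
  table <- validate_survival_table(table)
  if (sum(table$event) < 10) {
    warning("fewer than 10 events; Cox estimates may be unstable")
  }
  keep <- covariates[vapply(covariates, function(v) {
    x <- table[[v]]
    if (is.null(x)) stop("covariate not found: ", v)
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped)) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
  }
  if (!length(keep)) stop("no usable covariates")
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(sprintf("`%s`", keep), collapse = " + ")))
  fit <- survival::coxph(fml, data = table, ties = "breslow")
  s <- summary(fit)
  out <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    se = s$coefficients[, "se(coef)"],
                    z = s$coefficients[, "z"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' High- versus low-tertile survival comparison
#'
#' Mid-tertile samples are excluded; Kaplan-Meier curves and the log-rank
#' test compare the upper against the lower MNAI tertile.
#'
#' @param table survival table with sample_id.
#' @param mnai_result data.frame(sample_id, mnai, tertile).
#' @return list(km (per-group KM estimates), logrank, n_high, n_low).
#' @export
tertile_survival <- function(table, mnai_result) {
  m <- merge(table, mnai_result[, c("sample_id", "tertile")], by = "sample_id")
  m <- m[m$tertile %in% c("high", "low"), , drop = FALSE]
  m$tertile <- droplevels(factor(m$tertile, levels = c("low", "high")))
  km <- lapply(split(m, m$tertile), km_estimate)
  lr <- logrank_test(m, m$tertile)
  list(km = km, logrank = lr,
       n_high = sum(m$tertile == "high"), n_low = sum(m$tertile == "low"))
}
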