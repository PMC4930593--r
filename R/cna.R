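# Copy-number region merging, state calling, the one-at-a-time ANOVA
# association scan against network-gene expression, and MNAI-ordered
# co-amplification output.

#' Merge adjacent copy-number probes into regions by profile similarity
#'
#' Greedy agglomerative merge along each chromosome: the next probe joins
#' the current region while the across-sample Euclidean distance between
#' its profile and the region's running mean profile, divided by
#' sqrt(n_samples), stays at or below `max_dissimilarity`. Merging never
#' crosses a chromosome boundary. This serves the same dimensionality-
#' reduction purpose as CGH-region merging of SNP/BAC platforms.
#'
#' @param values probes x samples log2-ratio matrix.
#' @param probe_info data.frame(probe_id, chrom, start, end), sorted by
#'   (chrom block, position).
#' @param max_dissimilarity RMS profile distance allowed within a region.
#' @return a `cna_region_set`: list(regions (region_id, chrom, start, end,
#'   n_probes), signal (regions x samples mean log2 ratio), probe_region
#'   (region id per probe)).
#' @export
merge_regions <- function(values, probe_info, max_dissimilarity = 0.2) {
  stopifnot(nrow(values) == nrow(probe_info),
            all(rownames(values) == probe_info$probe_id))
  by_chrom <- split(seq_len(nrow(probe_info)), probe_info$chrom)
  for (idx in by_chrom) {
    if (is.unsorted(probe_info$start[idx], strictly = FALSE)) {
      stop("probes are not sorted by position within chromosome; sort the input")
    }
  }
  n_samp <- ncol(values)
  probe_region <- character(nrow(probe_info))
  regions <- list()
  rid <- 0
  for (chrom in unique(probe_info$chrom)) {
    idx <- which(probe_info$chrom == chrom)
    cur_members <- idx[1]
    cur_mean <- values[idx[1], ]
    flush <- function(members, mean_profile) {
      rid <<- rid + 1
      regions[[rid]] <<- list(
        region_id = sprintf("R%04d", rid), chrom = chrom,
        start = min(probe_info$start[members]),
        end = max(probe_info$end[members]),
        n_probes = length(members), members = members,
        signal = mean_profile)
      probe_region[members] <<- sprintf("R%04d", rid)
    }
    for (i in idx[-1]) {
      d <- sqrt(sum((values[i, ] - cur_mean)^2)) / sqrt(n_samp)
      if (d <= max_dissimilarity) {
        cur_members <- c(cur_members, i)
        k <- length(cur_members)
        cur_mean <- cur_mean + (values[i, ] - cur_mean) / k
      } else {
        flush(cur_members, cur_mean)
        cur_members <- i
        cur_mean <- values[i, ]
      }
    }
    flush(cur_members, cur_mean)
  }
  signal <- do.call(rbind, lapply(regions, `[[`, "signal"))
  rownames(signal) <- vapply(regions, `[[`, "", "region_id")
  colnames(signal) <- colnames(values)
  reg_df <- do.call(rbind, lapply(regions, function(r) {
    data.frame(region_id = r$region_id, chrom = r$chrom, start = r$start,
               end = r$end, n_probes = r$n_probes, stringsAsFactors = FALSE)
  }))
  structure(list(regions = reg_df, signal = signal, probe_region = probe_region),
            class = "cna_region_set")
}

#' Call categorical copy-number states from region log2 ratios
#'
#' value <= loss -> "loss"; value >= amp -> "amp"; value >= gain -> "gain";
#' otherwise "neutral".
#'
#' @param signal numeric matrix (or vector) of region log2 ratios.
#' @param thresholds named vector c(loss, gain, amp) with loss < 0 < gain <
#'   amp.
#' @return character matrix/vector of states.
#' @export
call_states <- function(signal, thresholds = c(loss = -0.3, gain = 0.3, amp = 0.8)) {
  if (!(thresholds["loss"] < 0 && 0 < thresholds["gain"] &&
        thresholds["gain"] < thresholds["amp"])) {
    stop("non-monotone thresholds: need loss < 0 < gain < amp")
  }
  out <- ifelse(signal <= thresholds["loss"], "loss",
                ifelse(signal >= thresholds["amp"], "amp",
                       ifelse(signal >= thresholds["gain"], "gain", "neutral")))
  if (is.matrix(signal)) dimnames(out) <- dimnames(signal)
  out
}

tier_rule <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-20, "strong",
                ifelse(p < 1e-10, "moderate",
                       ifelse(p < 1e-7, "weak", "ns"))))
}

#' One-at-a-time ANOVA scan of CNA states against gene expression
#'
#' For each (gene, region) pair a one-way ANOVA of the gene's expression
#' across the region's copy-number state categories. State categories with
#' fewer than 3 samples are merged into "neutral" (logged); regions left
#' with fewer than 2 categories of >= 3 samples are marked untested.
#' Significance tiers follow the heat-map convention: p < 1e-20 strong,
#' [1e-20, 1e-10) moderate, [1e-10, 1e-7) weak, else ns. A Bonferroni
#' column is reported for reference but never gates the tiers.
#'
#' @param expression genes x samples matrix (collapsed).
#' @param states regions x samples character matrix of CNA calls.
#' @param continuous if TRUE, regress expression on the continuous region
#'   signal instead of categorical states (then `states` must be numeric).
#' @return an `association_matrix`: list(p (genes x regions), tier, F,
#'   untested, notes, bonferroni_p).
#' @export
association_scan <- function(expression, states, continuous = FALSE) {
  shared <- intersect(colnames(expression), colnames(states))
  if (!length(shared)) stop("no shared samples between expression and states")
  expression <- expression[, shared, drop = FALSE]
  states <- states[, shared, drop = FALSE]
  genes <- rownames(expression)
  regions <- rownames(states)
  P <- matrix(NA_real_, length(genes), length(regions),
              dimnames = list(genes, regions))
  Fm <- P
  untested <- setNames(rep(FALSE, length(regions)), regions)
  notes <- list()
  for (j in seq_along(regions)) {
    if (continuous) {
      x <- as.numeric(states[j, ])
      if (stats::var(x) == 0) { untested[j] <- TRUE; next }
      for (i in seq_along(genes)) {
        ct <- cor.test(expression[i, ], x)
        P[i, j] <- ct$p.value
        Fm[i, j] <- unname(ct$statistic)^2
      }
      next
    }
    g <- states[j, ]
    counts <- table(g)
    small <- names(counts)[counts < 3]
    if (length(small) && !identical(small, "neutral")) {
      g[g %in% small] <- "neutral"
      notes[[regions[j]]] <- paste0("categories merged into neutral: ",
                                    paste(setdiff(small, "neutral"), collapse = ", "))
      counts <- table(g)
    }
    usable <- counts[counts >= 3]
    if (length(usable) < 2) { untested[j] <- TRUE; next }
    fg <- factor(g)
    for (i in seq_along(genes)) {
      fit <- oneway.test(expression[i, ] ~ fg, var.equal = TRUE)
      P[i, j] <- fit$p.value
      Fm[i, j] <- unname(fit$statistic)
    }
  }
  if (all(untested)) warning("no testable region; association matrix is empty")
  structure(list(p = P, tier = structure(tier_rule(P), dim = dim(P),
                                         dimnames = dimnames(P)),
                 F = Fm, untested = untested, notes = notes,
                 bonferroni_p = pmin(P * sum(is.finite(P)), 1)),
            class = "association_matrix")
}

#' Order samples by MNAI for co-amplification display
#'
#' @param states regions x samples CNA state matrix (driver regions).
#' @param mnai_result data.frame(sample_id, mnai) as from [compute_mnai()].
#' @return list(sample_order (ids, descending MNAI, stable ties),
#'   states_ordered, amp_count (amp states per sample, in that order)).
#' @export
coamplification_order <- function(states, mnai_result) {
  shared <- intersect(colnames(states), mnai_result$sample_id)
  mn <- mnai_result[match(shared, mnai_result$sample_id), ]
  ord <- order(-mn$mnai) # stable
  ids <- mn$sample_id[ord]
  st <- states[, ids, drop = FALSE]
  list(sample_order = ids, states_ordered = st,
       amp_count = colSums(st == "amp"))
}
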