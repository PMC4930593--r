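# Probe-to-gene collapsing by annotation quality, the MNAI, tertile
# assignment and the subtype ANOVA.

#' Collapse probes to gene-level expression by annotation quality
#'
#' Per gene: the mean over its "perfect" and "good" probes; if none exist
#' but at least one "bad" probe does, the mean over the bad probes (flagged
#' `bad_only`). Genes with no probe at all are reported absent.
#'
#' @param dataset an `expression_dataset`.
#' @param gene_list genes to collapse.
#' @return list with `values` (genes x samples matrix, absent genes
#'   dropped) and `flags` data.frame(gene, status in ok/bad_only/absent,
#'   n_probes_used).
#' @export
collapse_probes <- function(dataset, gene_list) {
  stopifnot(length(gene_list) >= 1)
  pi <- dataset$probe_info
  flags <- data.frame(gene = gene_list, status = "absent", n_probes_used = 0L,
                      stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_along(gene_list)) {
    g <- gene_list[i]
    idx <- which(pi$gene == g)
    if (!length(idx)) next
    good <- idx[pi$quality[idx] %in% c("perfect", "good")]
    use <- if (length(good)) good else idx
    flags$status[i] <- if (length(good)) "ok" else "bad_only"
    flags$n_probes_used[i] <- length(use)
    v <- dataset$values[use, , drop = FALSE]
    rows[[g]] <- if (nrow(v) == 1) v[1, ] else colMeans(v)
  }
  values <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    matrix(numeric(0), nrow = 0, ncol = ncol(dataset$values),
           dimnames = list(NULL, colnames(dataset$values)))
  }
  list(values = values, flags = flags)
}

#' Compute the mitotic network activity index (MNAI)
#'
#' The MNAI of a sample is the plain sum of the collapsed log2 expression
#' values of the signature genes present in the matrix (no per-gene
#' z-scoring by default, so values are comparable only within a dataset).
#'
#' @param collapsed genes x samples matrix (e.g. from [collapse_probes()]).
#' @param signature_genes the signature gene set.
#' @param dataset_id identifier recorded in the result.
#' @param zscore if TRUE, z-score each gene across samples before summing
#'   (off by default, matching the index definition).
#' @return data.frame(sample_id, mnai, tertile, dataset_id,
#'   gene_count_used); attribute `missing_genes` lists absent signature
#'   genes.
#' @export
compute_mnai <- function(collapsed, signature_genes, dataset_id = "dataset",
                         zscore = FALSE) {
  present <- intersect(signature_genes, rownames(collapsed))
  if (!length(present)) stop("no signature genes present in the matrix")
  m <- collapsed[present, , drop = FALSE]
  if (zscore) m <- t(scale(t(m)))
  mnai <- colSums(m)
  res <- data.frame(sample_id = colnames(collapsed), mnai = mnai,
                    tertile = assign_tertiles(mnai),
                    dataset_id = dataset_id,
                    gene_count_used = length(present),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "missing_genes") <- setdiff(signature_genes, present)
  res
}

#' Assign tertile classes (low / mid / high) to a score vector
#'
#' Rank-based split into three groups whose sizes differ by at most one;
#' when the size is not divisible by three, extra samples go to the lower
#' groups first (low, then mid). Ties are broken by stable input order.
#'
#' @param x numeric score vector (length >= 3).
#' @return factor with levels low/mid/high; attribute `thresholds` holds
#'   the maximal score in the low and mid groups.
#' @export
assign_tertiles <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for tertile assignment")
  base <- n %/% 3
  rem <- n %% 3
  sizes <- c(low = base + (rem >= 1), mid = base + (rem >= 2), high = base)
  ord <- order(x) # stable for ties (radix)
  lab <- rep(c("low", "mid", "high"), times = sizes)
  out <- character(n)
  out[ord] <- lab
  boundary_vals <- x[ord][cumsum(sizes)[1:2]]
  if (any(vapply(boundary_vals, function(b) sum(x == b) > 1, logical(1)))) {
    warning("tied scores span a tertile boundary; split by stable input order")
  }
  f <- factor(out, levels = c("low", "mid", "high"))
  attr(f, "thresholds") <- c(low_max = boundary_vals[1], mid_max = boundary_vals[2])
  f
}

#' One-way ANOVA of a score across subtype groups
#'
#' Classic equal-variance one-way ANOVA (F with k-1 and N-k df). Groups
#' with fewer than 2 samples are dropped with a warning.
#'
#' @param values numeric vector (e.g. MNAI values).
#' @param groups group labels, same length.
#' @return list(F, p, df1, df2, dropped_groups).
#' @export
subtype_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("dropping group(s) with <2 samples: ", paste(small, collapse = ", "))
    sel <- !(groups %in% small)
    values <- values[sel]
    groups <- groups[sel]
  }
  if (length(unique(groups)) < 2) stop("need at least 2 usable groups")
  fit <- oneway.test(values ~ factor(groups), var.equal = TRUE)
  list(F = unname(fit$statistic), p = fit$p.value,
       df1 = unname(fit$parameter[1]), df2 = unname(fit$parameter[2]),
       dropped_groups = small)
}
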