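# Seed-anchored co-expression relevance network: probe-seed correlations,
# permutation-null correlation threshold, network construction and
# conservation across cohorts.

# Row-standardize a probes x samples matrix for fast Pearson computation;
# returns NULL rows removed and the exclusion report.
standardize_rows <- function(values, min_pairs = 3) {
  n_ok <- rowSums(is.finite(values))
  v <- apply(values, 1, function(r) stats::var(r[is.finite(r)]))
  excluded <- data.frame(probe_id = rownames(values), reason = NA_character_,
                         stringsAsFactors = FALSE)
  excluded$reason[n_ok < min_pairs] <- "fewer than 3 complete pairs"
  excluded$reason[is.na(excluded$reason) & (!is.finite(v) | v == 0)] <- "zero variance"
  keep <- is.na(excluded$reason)
  list(values = values[keep, , drop = FALSE],
       excluded = excluded[!keep, , drop = FALSE])
}

# Collapsed profiles of the seed genes; errors if any seed is unmeasured.
seed_profiles <- function(dataset, seeds) {
  missing <- setdiff(seeds, dataset$probe_info$gene)
  if (length(missing)) {
    stop("seed gene(s) absent from annotation: ", paste(missing, collapse = ", "))
  }
  collapse_probes(dataset, seeds)$values
}

#' Pearson correlation of every probe with each seed-gene profile
#'
#' Seeds are collapsed to gene level first; correlations are
#' pairwise-complete. Probes with zero variance or fewer than 3 complete
#' pairs are excluded with a logged reason.
#'
#' @param dataset an `expression_dataset`.
#' @param seeds seed gene symbols (default PLK1, CENPE, AURKB).
#' @return data.frame(probe, seed, r, n_pairs); attribute `excluded` is the
#'   exclusion report.
#' @export
compute_seed_correlations <- function(dataset, seeds = SEED_GENES) {
  sp <- seed_profiles(dataset, seeds)
  std <- standardize_rows(dataset$values)
  for (i in seq_len(nrow(std$excluded))) {
    warning("probe ", std$excluded$probe_id[i], " excluded: ", std$excluded$reason[i])
  }
  X <- std$values
  has_na <- anyNA(X) || anyNA(sp)
  use <- if (has_na) "pairwise.complete.obs" else "everything"
  R <- cor(t(X), t(sp), use = use)
  n_pairs <- if (has_na) {
    ok_x <- is.finite(t(X))
    ok_s <- is.finite(t(sp))
    crossprod(ok_x, ok_s)
  } else {
    matrix(ncol(X), nrow = nrow(X), ncol = nrow(sp))
  }
  out <- data.frame(
    probe = rep(rownames(X), times = nrow(sp)),
    seed = rep(rownames(sp), each = nrow(X)),
    r = as.vector(R),
    n_pairs = as.vector(n_pairs),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- std$excluded
  out
}

#' Permutation-null correlation threshold for the relevance network
#'
#' For each of `n_perm` permutations the sample order of the seed profiles
#' is shuffled (destroying seed-gene coupling while preserving gene-gene
#' structure) and all probe-seed correlations recomputed. All null |r|
#' values are pooled across probes, seeds and permutations and the
#' threshold is the empirical (1 - alpha) quantile of the pool, so alphas
#' as small as 1 / (n_perm * n_probes * n_seeds) are resolvable.
#'
#' @param dataset an `expression_dataset`.
#' @param seeds seed gene symbols.
#' @param n_perm number of permutations (>= 1).
#' @param alpha tail probability in (0, 1).
#' @param rng_seed RNG seed for the permutation stream.
#' @return list(threshold_r, alpha, n_perm, resolution, n_null).
#' @export
permutation_null_threshold <- function(dataset, seeds = SEED_GENES,
                                       n_perm = 1000, alpha = 2.5e-5,
                                       rng_seed = 1) {
  stopifnot(n_perm >= 1, alpha > 0, alpha < 1)
  sp <- seed_profiles(dataset, seeds)
  std <- standardize_rows(dataset$values)
  X <- std$values
  n_null <- as.double(n_perm) * nrow(X) * nrow(sp)
  if (alpha < 1 / n_null) {
    stop(sprintf(
      "alpha = %g is below the pooled-null resolution 1/%g; increase n_perm",
      alpha, n_null))
  }
  n <- ncol(X)
  has_na <- anyNA(X) || anyNA(sp)
  use <- if (has_na) "pairwise.complete.obs" else "everything"
  tX <- t(X)
  null_abs <- with_seed(rng_seed, {
    out <- vector("list", n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      out[[b]] <- abs(as.vector(cor(tX, t(sp[, perm, drop = FALSE]), use = use)))
    }
    unlist(out)
  })
  null_abs <- null_abs[is.finite(null_abs)]
  thr <- unname(quantile(null_abs, probs = 1 - alpha, type = 1, names = FALSE))
  list(threshold_r = thr, alpha = alpha, n_perm = n_perm,
       resolution = 1 / n_null, n_null = length(null_abs))
}

#' Build the seed-anchored relevance network at a correlation threshold
#'
#' A gene enters the node set when at least one of its collapse-eligible
#' probes has |r| >= `threshold_r` with at least one seed; seeds present in
#' the dataset are always nodes. Edges connect every pair of node genes
#' whose collapsed profiles have |r| >= `threshold_r` (the same shared
#' threshold; |r| exactly at the threshold is included).
#'
#' @param dataset an `expression_dataset`.
#' @param seeds seed gene symbols.
#' @param threshold_r correlation threshold in (0, 1].
#' @return a `relevance_network`: list(nodes, edges (gene_a < gene_b, r),
#'   seeds, threshold_r, dataset_id, seed_correlations).
#' @export
build_relevance_network <- function(dataset, seeds = SEED_GENES, threshold_r) {
  stopifnot(threshold_r > 0, threshold_r <= 1)
  sc <- suppressWarnings(compute_seed_correlations(dataset, seeds))
  # restrict to probes the collapse rule would use
  pi <- dataset$probe_info
  is_good <- pi$quality %in% c("perfect", "good")
  gene_has_good <- tapply(is_good, pi$gene, any)
  eligible_probes <- pi$probe_id[is_good | !gene_has_good[pi$gene]]
  hits <- sc[sc$probe %in% eligible_probes & is.finite(sc$r) &
               abs(sc$r) >= threshold_r, , drop = FALSE]
  node_genes <- unique(pi$gene[match(hits$probe, pi$probe_id)])
  node_genes <- union(node_genes, intersect(seeds, pi$gene))
  if (!length(node_genes)) {
    warning("no gene passed the threshold; returning an empty network")
    return(structure(list(nodes = character(0),
                          edges = data.frame(gene_a = character(), gene_b = character(),
                                             r = numeric(), stringsAsFactors = FALSE),
                          seeds = seeds, threshold_r = threshold_r,
                          dataset_id = dataset$dataset_id,
                          seed_correlations = sc),
                     class = "relevance_network"))
  }
  collapsed <- collapse_probes(dataset, sort(node_genes))$values
  edges <- gene_pair_edges(collapsed, threshold_r)
  structure(list(nodes = sort(node_genes), edges = edges, seeds = seeds,
                 threshold_r = threshold_r, dataset_id = dataset$dataset_id,
                 seed_correlations = sc),
            class = "relevance_network")
}

# All unique gene pairs with |r| >= threshold on a collapsed matrix.
gene_pair_edges <- function(collapsed, threshold_r) {
  if (nrow(collapsed) < 2) {
    return(data.frame(gene_a = character(), gene_b = character(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  use <- if (anyNA(collapsed)) "pairwise.complete.obs" else "everything"
  R <- cor(t(collapsed), use = use)
  idx <- which(upper.tri(R) & is.finite(R) & abs(R) >= threshold_r, arr.ind = TRUE)
  data.frame(gene_a = rownames(R)[idx[, 1]], gene_b = rownames(R)[idx[, 2]],
             r = R[idx], stringsAsFactors = FALSE)
}

#' @export
print.relevance_network <- function(x, ...) {
  cat(sprintf("relevance_network '%s': %d nodes, %d edges (|r| >= %.4f; seeds: %s)\n",
              x$dataset_id, length(x$nodes), nrow(x$edges), x$threshold_r,
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

#' Conserve candidate network genes across datasets
#'
#' A candidate gene is retained iff, in every dataset, it is measured and
#' its collapsed profile reaches |r| >= that dataset's threshold with at
#' least one other candidate gene (it stays connected in the
#' dataset-restricted relevance network). Genes unmeasured in a dataset are
#' dropped with reason "absent", distinct from "disconnected".
#'
#' @param datasets list of `expression_dataset` (>= 1).
#' @param candidate_genes candidate gene set from the discovery network.
#' @param thresholds per-dataset correlation thresholds (recycled if
#'   length 1).
#' @return a `conserved_network`: list(gene_ids, support (genes x datasets
#'   logical), dropped (gene, dataset, reason), metadata).
#' @export
conserve_across_datasets <- function(datasets, candidate_genes, thresholds) {
  stopifnot(length(datasets) >= 1, length(candidate_genes) >= 1)
  thresholds <- rep_len(thresholds, length(datasets))
  candidate_genes <- unique(candidate_genes)
  support <- matrix(FALSE, nrow = length(candidate_genes), ncol = length(datasets),
                    dimnames = list(candidate_genes,
                                    vapply(datasets, function(d) d$dataset_id, "")))
  dropped <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    measured <- intersect(candidate_genes, ds$probe_info$gene)
    absent <- setdiff(candidate_genes, measured)
    for (g in absent) {
      dropped[[length(dropped) + 1]] <- data.frame(
        gene = g, dataset = ds$dataset_id, reason = "absent",
        stringsAsFactors = FALSE)
    }
    if (length(measured) >= 2) {
      collapsed <- collapse_probes(ds, measured)$values
      use <- if (anyNA(collapsed)) "pairwise.complete.obs" else "everything"
      R <- abs(cor(t(collapsed), use = use))
      diag(R) <- NA
      connected <- apply(R, 1, function(r) any(r >= thresholds[d], na.rm = TRUE))
      support[names(connected)[connected], d] <- TRUE
      for (g in names(connected)[!connected]) {
        dropped[[length(dropped) + 1]] <- data.frame(
          gene = g, dataset = ds$dataset_id, reason = "disconnected",
          stringsAsFactors = FALSE)
      }
    } else if (length(measured) == 1) {
      dropped[[length(dropped) + 1]] <- data.frame(
        gene = measured, dataset = ds$dataset_id, reason = "disconnected",
        stringsAsFactors = FALSE)
    }
  }
  retained <- rownames(support)[rowSums(support) == ncol(support)]
  structure(list(
    gene_ids = retained, support = support,
    dropped = if (length(dropped)) do.call(rbind, dropped) else
      data.frame(gene = character(), dataset = character(), reason = character()),
    metadata = list(
      thresholds = thresholds,
      dataset_ids = colnames(support),
      rule = "connectivity: |r| >= per-dataset threshold with >=1 other candidate in every dataset"
    )), class = "conserved_network")
}

#' @export
print.conserved_network <- function(x, ...) {
  cat(sprintf("conserved_network: %d of %d candidate genes retained across %d dataset(s)\n",
              length(x$gene_ids), nrow(x$support), ncol(x$support)))
  invisible(x)
}
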