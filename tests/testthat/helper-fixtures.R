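# Shared fixtures: tiny configs and hand-built datasets.

tiny_config <- function(...) {
  synthetic_config(n_samples = c(30, 40), n_genes = 200, module_size = 20,
                   seed = 101, ...)
}

# Build an expression_dataset from a genes x samples matrix with one
# "perfect" probe per gene (probe id == gene id unless renamed).
toy_dataset <- function(values, quality = NULL, id = "toy") {
  if (is.null(rownames(values))) rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(quality)) quality <- rep("perfect", nrow(values))
  expression_dataset(
    values,
    data.frame(probe_id = rownames(values), gene = rownames(values),
               quality = quality, stringsAsFactors = FALSE),
    dataset_id = id
  )
}

# Independent brute-force Pearson edge filter used as an oracle.
brute_force_edges <- function(collapsed, threshold) {
  genes <- rownames(collapsed)
  out <- list()
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (j <= i) next
    r <- cor(collapsed[i, ], collapsed[j, ])
    if (is.finite(r) && abs(r) >= threshold) {
      out[[length(out) + 1]] <- data.frame(gene_a = genes[i], gene_b = genes[j],
                                           r = r, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(), r = numeric()))
  }
  do.call(rbind, out)
}

# Independent Match score evaluation by direct formula (no sliding).
brute_force_match <- function(pwm, window) {
  bases <- c("A", "C", "G", "T")
  b <- match(strsplit(window, "")[[1]], bases)
  f <- pwm$freq
  I <- pwm$info
  cur <- function(pos) {
    sum(vapply(pos, function(i) {
      fi <- if (is.na(b[i])) min(f[i, ]) else f[i, b[i]]
      I[i] * fi
    }, 0))
  }
  mx <- function(pos) sum(I[pos] * apply(f[pos, , drop = FALSE], 1, max))
  mn <- function(pos) sum(I[pos] * apply(f[pos, , drop = FALSE], 1, min))
  allp <- seq_len(pwm$length)
  core <- pwm$core_offset:(pwm$core_offset + 4)
  list(mss = (cur(allp) - mn(allp)) / (mx(allp) - mn(allp)),
       css = (cur(core) - mn(core)) / (mx(core) - mn(core)))
}
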