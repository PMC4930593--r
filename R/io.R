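# Typed containers and file-format readers/writers: expression TSV + probe
# annotation TSV, SEG (1-based inclusive), survival CSV, plate CSV, promoter
# FASTA, TSS BED (0-based half-open), PWM count-matrix text, SIF/GraphML.

#' Construct an expression dataset (probes x samples with annotation)
#'
#' @param values numeric matrix, probes x samples, log2 scale; rownames are
#'   probe ids, colnames sample ids.
#' @param probe_info data.frame with columns probe_id, gene, quality
#'   (perfect/good/bad) covering every row of `values`.
#' @param sample_info data.frame with column sample_id (plus metadata such as
#'   subtype, survival fields); defaults to bare ids.
#' @param dataset_id identifier string.
#' @return an `expression_dataset` object.
#' @export
expression_dataset <- function(values, probe_info, sample_info = NULL,
                               dataset_id = "dataset") {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  stopifnot(all(c("probe_id", "gene", "quality") %in% names(probe_info)))
  missing_annot <- setdiff(rownames(values), probe_info$probe_id)
  if (length(missing_annot)) {
    stop("probes without annotation: ", paste(head(missing_annot, 5), collapse = ", "))
  }
  if (!all(probe_info$quality %in% c("perfect", "good", "bad"))) {
    stop("probe quality must be one of perfect/good/bad")
  }
  if (is.null(sample_info)) {
    sample_info <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  }
  stopifnot(all(colnames(values) %in% sample_info$sample_id))
  probe_info <- probe_info[match(rownames(values), probe_info$probe_id), , drop = FALSE]
  rownames(probe_info) <- NULL
  structure(list(values = values, probe_info = probe_info,
                 sample_info = sample_info, dataset_id = dataset_id),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d probes (%d genes) x %d samples\n",
              x$dataset_id, nrow(x$values), length(unique(x$probe_info$gene)),
              ncol(x$values)))
  invisible(x)
}

#' Write / read an expression dataset as TSV + annotation TSV
#'
#' The expression file has a `probe_id` column then one column per sample;
#' the annotation file has probe_id, gene, quality.
#'
#' @param dataset an `expression_dataset`.
#' @param expr_path,annot_path file paths.
#' @return `write_expression` returns the paths invisibly; `read_expression`
#'   returns an `expression_dataset`.
#' @export
write_expression <- function(dataset, expr_path, annot_path) {
  df <- data.frame(probe_id = rownames(dataset$values), dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$probe_info[, c("probe_id", "gene", "quality")], annot_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, annot_path))
}

#' @rdname write_expression
#' @param dataset_id identifier for the read dataset.
#' @export
read_expression <- function(expr_path, annot_path, dataset_id = basename(expr_path)) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") {
    stop("malformed expression header in ", expr_path, ": first column must be probe_id")
  }
  dup <- names(df)[-1][duplicated(names(df)[-1])]
  if (length(dup)) stop("duplicated sample column(s): ", paste(unique(dup), collapse = ", "))
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop("non-numeric expression values in column '", names(df)[-1][bad], "'")
  }
  rownames(values) <- df$probe_id
  annot <- read.delim(annot_path, stringsAsFactors = FALSE)
  expression_dataset(values, annot, dataset_id = dataset_id)
}

#' Write / read segmented copy-number profiles in SEG format
#'
#' SEG columns: sample, chrom, start, end, log2ratio with 1-based inclusive
#' coordinates; one row per (sample, segment).
#'
#' @param values probes x samples log2-ratio matrix.
#' @param probe_info data.frame(probe_id, chrom, start, end).
#' @param path file path.
#' @return `read_seg` returns list(values, probe_info) in probe order.
#' @export
write_seg <- function(values, probe_info, path) {
  stopifnot(all(rownames(values) == probe_info$probe_id))
  long <- do.call(rbind, lapply(colnames(values), function(s) {
    data.frame(sample = s, chrom = probe_info$chrom,
               start = probe_info$start, end = probe_info$end,
               log2ratio = values[, s], stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  seg <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(seg))) {
    stop("malformed SEG header: need columns ", paste(need, collapse = ", "))
  }
  bad <- which(seg$end < seg$start)
  if (length(bad)) {
    stop("SEG coordinate error (end < start) at data line(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  key <- paste(seg$chrom, seg$start, seg$end, sep = ":")
  ukey <- unique(key)
  samples <- unique(seg$sample)
  values <- matrix(NA_real_, nrow = length(ukey), ncol = length(samples),
                   dimnames = list(ukey, samples))
  values[cbind(match(key, ukey), match(seg$sample, samples))] <- seg$log2ratio
  first <- match(ukey, key)
  probe_info <- data.frame(probe_id = ukey, chrom = seg$chrom[first],
                           start = seg$start[first], end = seg$end[first],
                           stringsAsFactors = FALSE)
  ord <- order(probe_info$chrom, probe_info$start)
  list(values = values[ord, , drop = FALSE], probe_info = probe_info[ord, , drop = FALSE])
}

#' Write / read a survival table as CSV
#'
#' Columns: sample_id, time (months, > 0), event (1 = event, 0 = censored),
#' plus any metadata columns (e.g. subtype, group).
#'
#' @param table data.frame with at least sample_id, time, event.
#' @param path file path.
#' @export
write_survival <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab))) {
    stop("malformed survival header: need columns ", paste(need, collapse = ", "))
  }
  if (!all(tab$event %in% c(0, 1))) stop("event column must be 0/1")
  tab
}

#' Write / read dose-response plate tables as CSV
#'
#' Columns: cell_line, drug, dose_nM, rep1..repK, baseline, control.
#'
#' @param plates data.frame as produced by [generate_dose_response()].
#' @param path file path.
#' @export
write_plates <- function(plates, path) {
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plates
#' @export
read_plates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "dose_nM", "baseline", "control")
  if (!all(need %in% names(tab))) {
    stop("malformed plate header: need columns ", paste(need, collapse = ", "))
  }
  if (any(tab$dose_nM < 0)) {
    stop("negative dose at data line(s): ", paste(head(which(tab$dose_nM < 0), 5), collapse = ", "))
  }
  tab
}

#' Write / read promoter (or genome) sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read a TSS table as BED (0-based half-open)
#'
#' BED columns: chrom, start (= TSS, 0-based), end (= TSS + 1), name (gene),
#' score (0), strand.
#'
#' @param tss data.frame(chrom, tss, strand, gene).
#' @param path file path.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- data.frame(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1,
                    name = tss$gene, score = 0, strand = tss$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_bed
#' @export
read_tss_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], tss = bed[[2]], strand = bed[[6]],
             gene = bed[[4]], stringsAsFactors = FALSE)
}

#' Write / read PWM count matrices in a MEME-like text format
#'
#' Each motif block is `MOTIF <name>`, a header line `A C G T`, then one
#' line of 4 counts per position; blocks separated by blank lines.
#'
#' @param pwms list of `pwm` objects (or count matrices named in the list).
#' @param path file path.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwms)) {
    counts <- if (inherits(pwms[[nm]], "pwm")) pwms[[nm]]$counts else pwms[[nm]]
    writeLines(c(paste("MOTIF", nm), "A C G T"), con)
    writeLines(apply(counts, 1, function(r) {
      paste(format(r, trim = TRUE, digits = 15), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_pwms
#' @param pseudocount pseudocount for [build_pwm()] on read.
#' @export
read_pwms <- function(path, pseudocount = 0.25) {
  lines <- trimws(readLines(path))
  starts <- grep("^MOTIF ", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  out <- list()
  bounds <- c(starts, length(lines) + 1)
  for (i in seq_along(starts)) {
    name <- sub("^MOTIF ", "", lines[starts[i]])
    block <- lines[(starts[i] + 1):(bounds[i + 1] - 1)]
    block <- block[nzchar(block) & !grepl("^A C G T$", block)]
    counts <- do.call(rbind, lapply(strsplit(block, "\\s+"), as.numeric))
    colnames(counts) <- c("A", "C", "G", "T")
    out[[name]] <- build_pwm(counts, pseudocount = pseudocount, name = name)
  }
  out
}

#' Export a relevance network as SIF and/or GraphML (Cytoscape-compatible)
#'
#' SIF rows are `geneA pp geneB`, one per undirected edge; GraphML stores
#' the signed Pearson r as edge attribute `r`.
#'
#' @param network a `relevance_network`.
#' @param sif_path,graphml_path output paths (NULL to skip either).
#' @export
write_network <- function(network, sif_path = NULL, graphml_path = NULL) {
  edges <- network$edges
  if (!is.null(sif_path)) {
    lines <- if (nrow(edges)) {
      paste(edges$gene_a, "pp", edges$gene_b, sep = "\t")
    } else character(0)
    isolated <- setdiff(network$nodes, unique(c(edges$gene_a, edges$gene_b)))
    writeLines(c(lines, isolated), sif_path)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      if (nrow(edges)) edges[, c("gene_a", "gene_b", "r")] else
        data.frame(gene_a = character(), gene_b = character(), r = numeric()),
      directed = FALSE,
      vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(network)
}
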