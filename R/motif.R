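# Promoter extraction around the TSS and Match-style position weight
# matrix scanning with core (CSS) and matrix (MSS) similarity scores.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character vector of sequences.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Build a position weight matrix with information-weighted scoring terms
#'
#' Frequencies use a per-cell pseudocount; the per-position information
#' vector is `I(i) = sum_b f(i,b) * ln(4 f(i,b))` and the 5-position core
#' is the window of consecutive positions with maximal summed information.
#'
#' @param counts positions x 4 nonnegative count matrix (columns A,C,G,T).
#' @param pseudocount added to every cell (default 0.25).
#' @param name motif name.
#' @return a `pwm`: list(name, counts, freq, info, core_offset, length).
#' @export
build_pwm <- function(counts, pseudocount = 0.25, name = "pwm") {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4, all(counts >= 0))
  if (any(rowSums(counts) == 0)) stop("all-zero count row in PWM")
  if (nrow(counts) < 5) stop("PWM must have length >= 5 so the core is defined")
  colnames(counts) <- BASES
  freq <- (counts + pseudocount) / rowSums(counts + pseudocount)
  info <- rowSums(ifelse(freq > 0, freq * log(4 * freq), 0)) # 0 ln 0 = 0
  core_win <- nrow(counts) - 5 + 1
  core_sums <- vapply(seq_len(core_win), function(i) sum(info[i:(i + 4)]), 0)
  structure(list(name = name, counts = counts, freq = freq, info = info,
                 core_offset = which.max(core_sums), length = nrow(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, core at %d-%d, consensus %s\n",
              x$name, x$length, x$core_offset, x$core_offset + 4,
              pwm_consensus(x$counts)))
  invisible(x)
}

seq_to_int <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES) # NA for N etc.
}

# Information-weighted frequency lookup (4 x m), plus the per-position
# min/max used by the similarity normalization. N bases score the row
# minimum (conservative).
pwm_score_parts <- function(pwm, positions) {
  f <- pwm$freq[positions, , drop = FALSE]
  I <- pwm$info[positions]
  w <- t(f) * rep(I, each = 4) # 4 x m
  list(w = w, wmin = I * apply(f, 1, min), wmax = I * apply(f, 1, max))
}

# Raw Current scores of every window start for one strand.
slide_scores <- function(parts, ints) {
  m <- ncol(parts$w)
  L <- length(ints)
  if (L < m) return(numeric(0))
  ns <- L - m + 1
  cur <- numeric(ns)
  for (i in seq_len(m)) {
    col <- parts$w[, i]
    v <- col[ints[i:(i + ns - 1)]]
    v[is.na(v)] <- parts$wmin[i]
    cur <- cur + v
  }
  unname(cur)
}

#' Match similarity scores of a PWM against one sequence window
#'
#' `MSS = (Current - Min) / (Max - Min)` with
#' `Current = sum_i I(i) f(i, b_i)`, Max/Min the best/worst attainable
#' sums; `CSS` is the same restricted to the 5 core positions. N bases
#' score the position minimum.
#'
#' @param pwm a `pwm`.
#' @param window character sequence of exactly the PWM's length.
#' @return list(css, mss).
#' @export
match_score <- function(pwm, window) {
  ints <- seq_to_int(window)
  if (length(ints) != pwm$length) {
    stop("window length ", length(ints), " != PWM length ", pwm$length)
  }
  all_pos <- seq_len(pwm$length)
  core_pos <- pwm$core_offset:(pwm$core_offset + 4)
  score_on <- function(positions) {
    parts <- pwm_score_parts(pwm, positions)
    cur <- slide_scores(parts, ints[positions])
    mx <- sum(parts$wmax); mn <- sum(parts$wmin)
    if (mx == mn) return(1)
    (cur - mn) / (mx - mn)
  }
  list(css = score_on(core_pos), mss = score_on(all_pos))
}

#' Extract promoter windows around TSSs from a genome
#'
#' The window covers positions -3000..+1000 around the TSS (4001 bases) in
#' transcript orientation: on the minus strand the mirrored genomic window
#' is taken and reverse-complemented. Windows truncated by contig ends are
#' flagged.
#'
#' @param genome named character vector of contig sequences (or a FASTA
#'   path readable by [read_fasta()]).
#' @param tss data.frame(chrom, tss (0-based), strand, gene).
#' @param upstream,downstream window extents (bases).
#' @return list(promoters (named character), flags data.frame(gene,
#'   truncated), skipped (genes whose contig is missing)).
#' @export
extract_promoters <- function(genome, tss, upstream = 3000, downstream = 1000) {
  if (length(genome) == 1 && file.exists(genome[1])) genome <- read_fasta(genome[1])
  stopifnot(all(tss$strand %in% c("+", "-")))
  promoters <- character(0)
  flags <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(tss))) {
    g <- tss$gene[i]
    if (!(tss$chrom[i] %in% names(genome))) { skipped <- c(skipped, g); next }
    ctg <- genome[[tss$chrom[i]]]
    L <- nchar(ctg)
    t0 <- tss$tss[i] # 0-based
    if (tss$strand[i] == "+") {
      a0 <- t0 - upstream; b0 <- t0 + downstream # 0-based inclusive
    } else {
      a0 <- t0 - downstream; b0 <- t0 + upstream
    }
    trunc <- a0 < 0 || b0 > L - 1
    a0 <- max(a0, 0); b0 <- min(b0, L - 1)
    s <- substr(ctg, a0 + 1, b0 + 1)
    if (tss$strand[i] == "-") s <- revcomp(s)
    promoters[g] <- s
    flags[[g]] <- data.frame(gene = g, truncated = trunc, stringsAsFactors = FALSE)
  }
  list(promoters = promoters, flags = do.call(rbind, flags), skipped = skipped)
}

#' Scan promoters with PWMs using Match core/matrix similarity thresholds
#'
#' Both strands are scanned; a hit requires CSS >= `css_threshold` and
#' MSS >= `mss_threshold` (defaults 1 and 0.85). Offsets are 1-based
#' window-start positions on the promoter's forward (transcript) strand
#' for both strands.
#'
#' @param pwms list of `pwm` objects.
#' @param promoters named character vector of promoter sequences.
#' @param css_threshold,mss_threshold thresholds in `[0, 1]`.
#' @return list(hits data.frame(gene, pwm, strand, offset, css, mss),
#'   edges data.frame(tf, gene) of distinct pairs with >= 1 hit).
#' @export
scan_promoters <- function(pwms, promoters, css_threshold = 1.0,
                           mss_threshold = 0.85) {
  stopifnot(css_threshold >= 0, css_threshold <= 1,
            mss_threshold >= 0, mss_threshold <= 1)
  if (!length(promoters)) {
    warning("empty promoter set")
    return(list(hits = data.frame(gene = character(), pwm = character(),
                                  strand = character(), offset = integer(),
                                  css = numeric(), mss = numeric()),
                edges = data.frame(tf = character(), gene = character())))
  }
  hits <- list()
  for (g in names(promoters)) {
    fwd <- seq_to_int(promoters[[g]])
    rev_ints <- rev(5L - ifelse(is.na(fwd), NA_integer_, fwd)) # revcomp in int space
    L <- length(fwd)
    for (pw in pwms) {
      m <- pw$length
      core_pos <- pw$core_offset:(pw$core_offset + 4)
      all_parts <- pwm_score_parts(pw, seq_len(m))
      mx_all <- sum(all_parts$wmax); mn_all <- sum(all_parts$wmin)
      core_parts <- pwm_score_parts(pw, core_pos)
      mx_core <- sum(core_parts$wmax); mn_core <- sum(core_parts$wmin)
      for (strand in c("+", "-")) {
        ints <- if (strand == "+") fwd else rev_ints
        cur_all <- slide_scores(all_parts, ints)
        if (!length(cur_all)) next
        mss <- if (mx_all > mn_all) (cur_all - mn_all) / (mx_all - mn_all) else
          rep(1, length(cur_all))
        # core score of window starting at s uses bases s+core_offset-1 ..
        core_curs <- slide_scores(core_parts, ints)
        ns <- length(cur_all)
        core_for_window <- core_curs[seq_len(ns) + pw$core_offset - 1L]
        css <- if (mx_core > mn_core) (core_for_window - mn_core) / (mx_core - mn_core) else
          rep(1, ns)
        pass <- which(css >= css_threshold - 1e-12 & mss >= mss_threshold - 1e-12)
        if (length(pass)) {
          offset <- if (strand == "+") pass else (L - m + 2L) - pass
          hits[[length(hits) + 1]] <- data.frame(
            gene = g, pwm = pw$name, strand = strand, offset = offset,
            css = css[pass], mss = mss[pass], stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(), pwm = character(), strand = character(),
               offset = integer(), css = numeric(), mss = numeric())
  edges <- unique(hits[, c("pwm", "gene")])
  names(edges) <- c("tf", "gene")
  rownames(edges) <- NULL
  list(hits = hits, edges = edges)
}
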