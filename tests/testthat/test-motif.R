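test_that("PWM construction: information content and core selection", {
  # uniform row -> I = 0; single-base row with zero pseudocount -> ln 4
  counts <- rbind(c(25, 25, 25, 25), c(100, 0, 0, 0),
                  c(100, 0, 0, 0), c(100, 0, 0, 0), c(25, 25, 25, 25))
  pwm0 <- build_pwm(counts, pseudocount = 0)
  expect_equal(pwm0$info[1], 0)
  expect_equal(pwm0$info[2], log(4))
  expect_error(build_pwm(counts[1:4, ]), "length >= 5")
  expect_error(build_pwm(rbind(counts, c(0, 0, 0, 0))), "all-zero")

  # 6-position toy: core offset equals brute-force max over both windows
  counts6 <- rbind(c(10, 10, 10, 10), c(97, 1, 1, 1), c(97, 1, 1, 1),
                   c(1, 97, 1, 1), c(1, 1, 97, 1), c(90, 4, 3, 3))
  pwm6 <- build_pwm(counts6)
  sums <- c(sum(pwm6$info[1:5]), sum(pwm6$info[2:6]))
  expect_identical(pwm6$core_offset, unname(which.max(sums)))
  expect_true(all(pwm6$info >= 0))
  expect_equal(rowSums(pwm6$freq), rep(1, 6), tolerance = 1e-9)
})

test_that("match scores: consensus, anti-consensus and exhaustive oracle", {
  counts <- rbind(c(70, 10, 10, 10), c(40, 40, 10, 10), c(10, 70, 10, 10),
                  c(10, 10, 70, 10), c(10, 10, 10, 70))
  pwm <- build_pwm(counts, pseudocount = 0)
  expect_equal(match_score(pwm, "AACGT")$mss, 1.0) # consensus -> Max
  expect_equal(match_score(pwm, "AACGT")$css, 1.0)
  # anti-consensus (min base each position; position 2 min is G or T)
  expect_equal(match_score(pwm, "CGTAA")$mss, 0)
  expect_error(match_score(pwm, "AAAA"), "length")

  # exhaustive oracle over all sequences for motif length 5
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(bases, bases, bases, bases, bases)
  seqs <- apply(combos[sample(nrow(combos), 64), ], 1, paste, collapse = "")
  for (s in seqs) {
    got <- match_score(pwm, s)
    want <- brute_force_match(pwm, s)
    expect_equal(got$mss, want$mss, tolerance = 1e-12)
    expect_equal(got$css, want$css, tolerance = 1e-12)
    expect_gte(got$mss, 0); expect_lte(got$mss, 1)
  }
})

test_that("promoter extraction: window arithmetic, strands, truncation", {
  ctg <- paste(rep(c("A", "C", "G", "T"), 2500), collapse = "") # 10 kb
  genome <- c(chrA = ctg)
  tss <- data.frame(chrom = "chrA", tss = 3000, strand = "+", gene = "g1")
  ex <- extract_promoters(genome, tss)
  expect_identical(nchar(ex$promoters[["g1"]]), 4001L)
  expect_identical(ex$promoters[["g1"]], substr(ctg, 1, 4001)) # [0, 4001)
  expect_false(ex$flags$truncated)

  # minus strand on a palindromic toy: A<->T, C<->G
  pal <- c(chrB = paste(rep("ACGT", 25), collapse = "")) # 100 bp
  tss_m <- data.frame(chrom = "chrB", tss = 50, strand = "-", gene = "g2")
  ex_m <- extract_promoters(pal, tss_m, upstream = 10, downstream = 5)
  # genomic window [45, 60] reverse-complemented
  expect_identical(ex_m$promoters[["g2"]],
                   revcomp(substr(pal, 46, 61)))
  expect_identical(nchar(ex_m$promoters[["g2"]]), 16L)

  # TSS near contig start -> truncated + flagged
  tss_t <- data.frame(chrom = "chrA", tss = 100, strand = "+", gene = "g3")
  ex_t <- extract_promoters(genome, tss_t)
  expect_true(ex_t$flags$truncated)
  expect_identical(nchar(ex_t$promoters[["g3"]]), 1101L)

  # missing contig is skipped with a report
  tss_x <- data.frame(chrom = "nope", tss = 10, strand = "+", gene = "g4")
  expect_identical(extract_promoters(genome, tss_x)$skipped, "g4")
})

test_that("promoter scan: counting, planted recovery and monotonicity", {
  pwms <- mitonet:::synthetic_pwms()
  pw <- pwms[[1]]
  prom <- with_seed(61, paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                              collapse = ""))
  # thresholds (0,0): every window on both strands is a hit
  res0 <- scan_promoters(list(pw), c(gX = prom), css_threshold = 0,
                         mss_threshold = 0)
  expect_identical(nrow(res0$hits), 2L * (200L - pw$length + 1L))
  # raising the MSS threshold never increases the hit count
  n_prev <- Inf
  for (thr in c(0.5, 0.7, 0.9, 1)) {
    n_now <- nrow(scan_promoters(list(pw), c(gX = prom), css_threshold = 0,
                                 mss_threshold = thr)$hits)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  # a planted consensus is found at its position with MSS = 1
  cons <- mitonet:::pwm_consensus(pw$counts)
  prom_p <- paste0(substr(prom, 1, 80), cons,
                   substr(prom, 81 + nchar(cons), 200))
  res <- scan_promoters(list(pw), c(gY = prom_p), css_threshold = 1,
                        mss_threshold = 0.99)
  expect_true(any(res$hits$offset == 81 & res$hits$strand == "+"))
  expect_true(all(res$hits$mss >= 0.99 - 1e-12))
  # empty promoter set warns and returns empty tables
  expect_warning(empty <- scan_promoters(list(pw), character(0)), "empty")
  expect_identical(nrow(empty$hits), 0L)
})

test_that("strand symmetry: scanning the reverse complement mirrors offsets", {
  pwms <- mitonet:::synthetic_pwms()
  pw <- pwms$FOXM1
  prom <- with_seed(62, paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                              collapse = ""))
  fwd <- scan_promoters(list(pw), c(g = prom), css_threshold = 0.8,
                        mss_threshold = 0.7)$hits
  rev <- scan_promoters(list(pw), c(g = revcomp(prom)), css_threshold = 0.8,
                        mss_threshold = 0.7)$hits
  expect_identical(nrow(fwd), nrow(rev))
  L <- 300L; m <- pw$length
  # a + hit at offset o corresponds to a - hit at L - m - o + 2 on the rc
  key_fwd <- sort(paste(ifelse(fwd$strand == "+", "-", "+"),
                        L - m - fwd$offset + 2L, round(fwd$mss, 10)))
  key_rev <- sort(paste(rev$strand, rev$offset, round(rev$mss, 10)))
  expect_identical(key_fwd, key_rev)
})

test_that("exhaustive window scan equals per-window match_score on toys", {
  pw <- build_pwm(rbind(c(80, 10, 5, 5), c(5, 80, 10, 5), c(5, 5, 80, 10),
                        c(10, 5, 5, 80), c(80, 5, 10, 5), c(20, 30, 25, 25)))
  prom <- with_seed(63, paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                              collapse = ""))
  res <- scan_promoters(list(pw), c(g = prom), css_threshold = 0,
                        mss_threshold = 0)
  fwd_hits <- res$hits[res$hits$strand == "+", ]
  fwd_hits <- fwd_hits[order(fwd_hits$offset), ]
  for (o in fwd_hits$offset) {
    win <- substr(prom, o, o + pw$length - 1)
    ms <- match_score(pw, win)
    expect_equal(fwd_hits$mss[fwd_hits$offset == o], ms$mss, tolerance = 1e-12)
    expect_equal(fwd_hits$css[fwd_hits$offset == o], ms$css, tolerance = 1e-12)
  }
})
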