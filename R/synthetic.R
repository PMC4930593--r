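# Synthetic multi-layer cohort generator. Plants a co-regulated mitotic
# module whose expression is driven by latent amplicon dosage at four
# genomic regions, with matched copy-number, survival, dose-response,
# promoter-motif and siRNA layers sharing the same per-sample truth.

# 54 canonical mitotic-apparatus gene symbols; the first three are the seeds.
MITOTIC_GENES <- c(
  "PLK1", "CENPE", "AURKB", "DEPDC1", "GTSE1", "FOXM1", "CCNB1", "CCNA2",
  "BUB1", "BUB1B", "TTK", "MELK", "PBK", "AURKA", "KIF14", "NCAPD2",
  "NCAPG", "NCAPH", "SMC4", "RRM2", "KIF2C", "DLGAP5", "HJURP", "NDC80",
  "PTTG1", "CHEK1", "EXO1", "RFC3", "TYMS", "MCM10", "KIF11", "KIF23",
  "CDK1", "CDC20", "CDCA8", "CENPA", "CENPF", "ESPL1", "INCENP", "KIF15",
  "KIF20A", "KIF4A", "NUSAP1", "PRC1", "SPAG5", "TPX2", "UBE2C", "BIRC5",
  "ASPM", "CEP55", "FAM83D", "ERCC6L", "RACGAP1", "MKI67"
)

SEED_GENES <- c("PLK1", "CENPE", "AURKB")

# Genes carried only by a "bad" probe (mirrors platforms where the sole
# available probe for a network gene is low quality).
BAD_ONLY_GENES <- c("DEPDC1", "GTSE1")

# The four recurrently amplified driver regions (Mb coordinates).
DRIVER_REGIONS <- data.frame(
  region_id = c("amp_8q24", "amp_10p15_p12", "amp_12p13", "amp_17q24_q25"),
  chrom = c("chr8", "chr10", "chr12", "chr17"),
  start_mb = c(120, 0, 0, 55.4),
  end_mb = c(132, 17.8, 4, 78.5),
  tf = c("MYC", "ZEB1", "FOXM1", "SOX9"),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the generator with validated defaults. The
#' defaults define the study conditions used throughout the analysis:
#' three cohorts of 60/100/200 samples, a 54-gene planted module whose
#' log2 expression is shifted by `beta_amp` per amplified driver region and
#' shares a latent factor of SD `module_factor_sd`, survival hazard
#' increasing with module activity and drug log10 GI50 decreasing with it.
#'
#' @param n_samples integer vector, samples per dataset.
#' @param n_genes total genes in the universe.
#' @param module_size number of planted module genes (includes the 3 seeds).
#' @param n_driver_regions number of amplicon driver regions (max 4 named).
#' @param amp_prob per-region per-sample amplification probability.
#' @param beta_amp log2 expression shift per amplified driver region.
#' @param module_factor_sd SD of the shared latent module factor.
#' @param noise_sd per-gene residual SD (log2 units).
#' @param hazard_log_hr log hazard ratio per SD of module activity.
#' @param gi50_slope log10 GI50 shift per SD of module activity (negative =
#'   high-activity lines are more sensitive).
#' @param probe_noise_sd measurement SD of a "perfect" probe; "good" probes
#'   get twice this, "bad" probes `bad_probe_sd`.
#' @param bad_probe_sd measurement SD of a "bad" probe.
#' @param baseline_hazard exponential baseline hazard (events per month).
#' @param censor_max upper bound of the uniform censoring window (months);
#'   the default yields roughly 30% censoring.
#' @param gi50_base base log10 GI50 in nM (100 nM).
#' @param dose_cv multiplicative CV of replicate luminescence wells.
#' @param seed master RNG seed; all layers derive their streams from it.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = c(60, 100, 200),
                             n_genes = 2000,
                             module_size = 54,
                             n_driver_regions = 4,
                             amp_prob = 0.25,
                             beta_amp = 0.8,
                             module_factor_sd = 1.0,
                             noise_sd = 0.5,
                             hazard_log_hr = 0.6,
                             gi50_slope = -0.4,
                             probe_noise_sd = 0.1,
                             bad_probe_sd = 1.0,
                             baseline_hazard = 0.05,
                             censor_max = 64,
                             gi50_base = 2,
                             dose_cv = 0.05,
                             seed = 20160701) {
  stopifnot(length(n_samples) >= 1, all(n_samples >= 3))
  if (module_size >= n_genes) {
    stop("invalid config: module_size must be smaller than n_genes")
  }
  if (amp_prob < 0 || amp_prob > 1) stop("invalid config: amp_prob must lie in [0,1]")
  if (module_factor_sd < 0 || noise_sd <= 0 || probe_noise_sd <= 0 || bad_probe_sd <= 0) {
    stop("invalid config: SDs must be positive")
  }
  if (n_driver_regions < 1 || n_driver_regions > nrow(DRIVER_REGIONS)) {
    stop("invalid config: n_driver_regions must be in 1..", nrow(DRIVER_REGIONS))
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    module_size = as.integer(module_size),
    n_driver_regions = as.integer(n_driver_regions),
    amp_prob = amp_prob, beta_amp = beta_amp,
    module_factor_sd = module_factor_sd, noise_sd = noise_sd,
    hazard_log_hr = hazard_log_hr, gi50_slope = gi50_slope,
    probe_noise_sd = probe_noise_sd, bad_probe_sd = bad_probe_sd,
    baseline_hazard = baseline_hazard, censor_max = censor_max,
    gi50_base = gi50_base, dose_cv = dose_cv,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

synthetic_gene_ids <- function(config) {
  m <- config$module_size
  module <- if (m <= length(MITOTIC_GENES)) {
    MITOTIC_GENES[seq_len(m)]
  } else {
    c(MITOTIC_GENES, sprintf("MNG%03d", seq_len(m - length(MITOTIC_GENES))))
  }
  background <- sprintf("BG%04d", seq_len(config$n_genes - m))
  c(module, background)
}

# Shared probe annotation: 1-3 probes per gene; DEPDC1/GTSE1 (when present)
# get a single "bad" probe; every other gene keeps at least one
# perfect-or-good probe so the collapse rule has something reliable.
synthetic_probe_table <- function(config) {
  genes <- synthetic_gene_ids(config)
  with_seed(sub_seed(config$seed, 1), {
    n_probes <- sample(1:3, length(genes), replace = TRUE, prob = c(0.35, 0.4, 0.25))
    n_probes[genes %in% BAD_ONLY_GENES] <- 1L
    rows <- lapply(seq_along(genes), function(i) {
      g <- genes[i]
      k <- n_probes[i]
      qual <- if (g %in% BAD_ONLY_GENES) {
        "bad"
      } else {
        c(sample(c("perfect", "good"), 1, prob = c(0.6, 0.4)),
          if (k > 1) sample(c("perfect", "good", "bad"), k - 1,
                            replace = TRUE, prob = c(0.5, 0.3, 0.2)))
      }
      data.frame(probe_id = sprintf("%s_p%d", g, seq_len(k)),
                 gene = g, quality = qual, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate synthetic expression cohorts with a planted mitotic module
#'
#' For each cohort, gene-level log2 expression follows
#' `x[g,s] = mu_g + beta_amp * sum_r A[r,s] + F_s + eps` for module genes
#' (background genes get `mu_g + eps` only), where `A[r,s]` are Bernoulli
#' amplicon indicators shared with the copy-number layer and `F_s` is the
#' latent module factor. Probe-level values add quality-dependent
#' measurement noise; probe annotation follows the perfect/good/bad scheme.
#'
#' @param config a [synthetic_config()].
#' @return a list with `datasets` (list of `expression_dataset`) and `truth`
#'   (module genes, driver regions, per-sample amplicon indicators and
#'   module activity per dataset).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- synthetic_gene_ids(config)
  module <- genes[seq_len(config$module_size)]
  probes <- synthetic_probe_table(config)
  regions <- DRIVER_REGIONS[seq_len(config$n_driver_regions), , drop = FALSE]

  mu <- with_seed(sub_seed(config$seed, 2), rnorm(length(genes), 7, 1))
  names(mu) <- genes

  datasets <- vector("list", length(config$n_samples))
  amp <- vector("list", length(config$n_samples))
  activity <- vector("list", length(config$n_samples))

  for (d in seq_along(config$n_samples)) {
    n <- config$n_samples[d]
    sample_ids <- sprintf("D%d_S%03d", d, seq_len(n))
    layer <- with_seed(sub_seed(config$seed, 10 + d), {
      A <- matrix(rbinom(nrow(regions) * n, 1, config$amp_prob),
                  nrow = nrow(regions), ncol = n,
                  dimnames = list(regions$region_id, sample_ids))
      F_s <- rnorm(n, 0, config$module_factor_sd)
      act <- config$beta_amp * colSums(A) + F_s
      is_mod <- genes %in% module
      shift <- outer(as.numeric(is_mod), act) # genes x samples
      eps <- matrix(rnorm(length(genes) * n, 0, config$noise_sd),
                    nrow = length(genes))
      G <- mu + shift + eps
      rownames(G) <- genes
      colnames(G) <- sample_ids
      probe_sd <- c(perfect = config$probe_noise_sd,
                    good = 2 * config$probe_noise_sd,
                    bad = config$bad_probe_sd)[probes$quality]
      P <- G[probes$gene, , drop = FALSE] +
        matrix(rnorm(nrow(probes) * n, 0, 1), nrow = nrow(probes)) * probe_sd
      rownames(P) <- probes$probe_id
      subtype <- ifelse(runif(n) < plogis(1.5 * scale_vec(act)), "basal", "luminal")
      list(A = A, act = act, P = P, subtype = subtype)
    })
    datasets[[d]] <- expression_dataset(
      values = layer$P, probe_info = probes,
      sample_info = data.frame(sample_id = sample_ids, subtype = layer$subtype,
                               stringsAsFactors = FALSE),
      dataset_id = sprintf("synthetic_%d", d)
    )
    amp[[d]] <- layer$A
    activity[[d]] <- setNames(layer$act, sample_ids)
  }

  truth <- list(
    module_genes = module, gene_ids = genes, seed_genes = SEED_GENES,
    driver_regions = regions, amp = amp, activity = activity,
    config = config
  )
  list(datasets = datasets, truth = truth)
}

scale_vec <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Generate segmented copy-number profiles matching the expression truth
#'
#' Tiles a five-chromosome genome with probes every 2 Mb. Probes inside a
#' driver region take log2 ratio ~ Normal(1, 0.1) in samples where that
#' region's amplicon indicator is 1 (the same indicators that drove
#' expression), Normal(0, 0.1) otherwise; background probes are always
#' Normal(0, 0.1).
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` component of [generate_expression()].
#' @param dataset index of the cohort whose samples to profile.
#' @return list with `probe_info` (probe_id, chrom, start, end in 1-based
#'   inclusive bp), `values` (probes x samples log2 ratios) and `amp`
#'   (the driver amplicon indicators used).
#' @export
generate_cna <- function(config, truth, dataset = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  A <- truth$amp[[dataset]]
  n <- ncol(A)
  chroms <- data.frame(
    chrom = c("chr1", "chr8", "chr10", "chr12", "chr17"),
    len_mb = c(100, 146, 135, 133, 81), stringsAsFactors = FALSE
  )
  tiles <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    starts <- seq(0, chroms$len_mb[i] - 2, by = 2)
    data.frame(chrom = chroms$chrom[i], start_mb = starts,
               end_mb = starts + 2, stringsAsFactors = FALSE)
  }))
  tiles$probe_id <- sprintf("cnp_%s_%04.0f", sub("chr", "", tiles$chrom),
                            tiles$start_mb)
  regions <- truth$driver_regions
  # region membership of each probe (midpoint rule)
  mid <- (tiles$start_mb + tiles$end_mb) / 2
  probe_region <- rep(NA_character_, nrow(tiles))
  for (r in seq_len(nrow(regions))) {
    hit <- tiles$chrom == regions$chrom[r] & mid >= regions$start_mb[r] &
      mid <= regions$end_mb[r]
    probe_region[hit] <- regions$region_id[r]
  }
  values <- with_seed(sub_seed(config$seed, 30 + dataset), {
    V <- matrix(rnorm(nrow(tiles) * n, 0, 0.1), nrow = nrow(tiles),
                dimnames = list(tiles$probe_id, colnames(A)))
    for (r in seq_len(nrow(regions))) {
      idx <- which(probe_region == regions$region_id[r])
      amp_samples <- which(A[regions$region_id[r], ] == 1)
      if (length(idx) && length(amp_samples)) {
        V[idx, amp_samples] <- V[idx, amp_samples] + 1.0
      }
    }
    V
  })
  probe_info <- data.frame(
    probe_id = tiles$probe_id, chrom = tiles$chrom,
    start = as.integer(tiles$start_mb * 1e6 + 1),
    end = as.integer(tiles$end_mb * 1e6),
    region_truth = probe_region, stringsAsFactors = FALSE
  )
  list(probe_info = probe_info, values = values, amp = A)
}

#' Generate survival times driven by module activity
#'
#' Times are exponential with hazard `h0 * exp(hazard_log_hr * z)` where `z`
#' is the standardized activity; censoring is independent uniform on
#' `[0, censor_max]` (roughly 30% censored at the defaults).
#'
#' @param config a [synthetic_config()].
#' @param activity named per-sample module activity (truth or MNAI).
#' @param seed optional RNG seed (defaults to a stream of `config$seed`).
#' @return data.frame(sample_id, time, event).
#' @export
generate_survival <- function(config, activity, seed = sub_seed(config$seed, 50)) {
  if (any(!is.finite(activity))) stop("non-finite activity values")
  z <- scale_vec(activity)
  with_seed(seed, {
    h <- config$baseline_hazard * exp(config$hazard_log_hr * z)
    t_event <- rexp(length(z), rate = h)
    t_cens <- runif(length(z), 0, config$censor_max)
    data.frame(
      sample_id = if (is.null(names(activity))) paste0("S", seq_along(z)) else names(activity),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE
    )
  })
}

#' The nine-dose 1:5 dilution grid from 30 uM, in nM
#' @return numeric vector of 9 doses, decreasing from 30000 nM.
#' @export
dose_grid <- function() 30000 / 5^(0:8)

#' Generate dose-response plates for cell lines with activity-linked GI50
#'
#' True log10 GI50 (nM) is `gi50_base + gi50_slope * z + Normal(0, 0.1)`;
#' wells follow a Hill slope-1 growth model between a time-0 baseline and an
#' untreated 72-h control, with multiplicative replicate noise.
#'
#' @param config a [synthetic_config()].
#' @param activity named per-cell-line module activity.
#' @param drugs drug names.
#' @param seed optional RNG seed.
#' @return list with `plates` (long data.frame: cell_line, drug, dose_nM,
#'   rep1..rep3, baseline, control) and `truth` (true GI50 per line/drug).
#' @export
generate_dose_response <- function(config, activity,
                                   drugs = c("GSK462364", "GSK923295", "GSK1070916"),
                                   seed = sub_seed(config$seed, 60)) {
  if (is.null(names(activity))) names(activity) <- paste0("CL", seq_along(activity))
  z <- scale_vec(activity)
  doses <- dose_grid()
  baseline <- 500
  control <- 2000
  with_seed(seed, {
    truth <- expand.grid(cell_line = names(activity), drug = drugs,
                         stringsAsFactors = FALSE)
    truth$log10_gi50 <- config$gi50_base +
      config$gi50_slope * z[truth$cell_line] + rnorm(nrow(truth), 0, 0.1)
    truth$gi50_nM <- 10^truth$log10_gi50
    plates <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      g <- truth$gi50_nM[i]
      gp <- 100 / (1 + doses / g) # Hill slope 1, crosses 50 at g
      T_mean <- baseline + (control - baseline) * gp / 100
      reps <- vapply(T_mean, function(m) {
        m * (1 + rnorm(3, 0, config$dose_cv))
      }, numeric(3))
      data.frame(cell_line = truth$cell_line[i], drug = truth$drug[i],
                 dose_nM = doses,
                 rep1 = reps[1, ], rep2 = reps[2, ], rep3 = reps[3, ],
                 baseline = baseline, control = control,
                 stringsAsFactors = FALSE)
    }))
    list(plates = plates, truth = truth)
  })
}

# Consensus sequence (top count per position) of a PWM count matrix.
pwm_consensus <- function(counts) {
  paste(c("A", "C", "G", "T")[apply(counts, 1, which.max)], collapse = "")
}

# Fixed synthetic count matrices for the four amplified TFs. Counts vary by
# position so the information content (and the 5-bp core) is non-trivial.
synthetic_pwms <- function() {
  build <- function(name, consensus, strong) {
    bases <- c("A", "C", "G", "T")
    m <- length(strong)
    counts <- matrix(0, nrow = m, ncol = 4, dimnames = list(NULL, bases))
    cons <- strsplit(consensus, "")[[1]]
    for (i in seq_len(m)) {
      counts[i, ] <- (100 - strong[i]) / 3
      counts[i, cons[i]] <- strong[i]
    }
    build_pwm(counts, name = name)
  }
  list(
    MYC = build("MYC", "CACGTGTC", c(90, 85, 92, 88, 90, 85, 70, 62)),
    ZEB1 = build("ZEB1", "CACCTGGT", c(85, 90, 88, 92, 90, 85, 65, 58)),
    FOXM1 = build("FOXM1", "TAAACAAT", c(80, 90, 92, 88, 85, 90, 64, 55)),
    SOX9 = build("SOX9", "AACAATGG", c(88, 90, 85, 92, 90, 80, 60, 66))
  )
}

#' Generate promoter sequences with planted TF binding motifs
#'
#' Each gene gets a 6001-base contig with a strand-aware TSS; the promoter
#' window is the 4001 bases spanning `[-3000, +1000]` around the TSS in
#' transcript orientation. Module-gene promoters carry 1-3 planted consensus
#' occurrences of each of the four synthetic TF matrices (MYC, ZEB1, FOXM1,
#' SOX9) at recorded positions.
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` component of [generate_expression()].
#' @param genes genes to emit promoters for (default: module genes plus 20
#'   background genes as scan controls).
#' @param plant_rate expected planted occurrences per (module gene, PWM);
#'   0 disables planting.
#' @param seed optional RNG seed.
#' @return list with `genome` (named character contigs), `tss` (BED-style
#'   0-based table: chrom, tss, strand, gene), `promoters` (named character,
#'   transcript-oriented), `pwms` and `planted` (gene, pwm, pos: 1-based
#'   offset of the consensus within the promoter window).
#' @export
generate_promoters <- function(config, truth,
                               genes = c(truth$module_genes,
                                         head(setdiff(truth$gene_ids, truth$module_genes), 20)),
                               plant_rate = 2,
                               seed = sub_seed(config$seed, 70)) {
  pwms <- synthetic_pwms()
  bases <- c("A", "C", "G", "T")
  win <- 4001L
  with_seed(seed, {
    genome <- list()
    tss_rows <- list()
    planted <- list()
    promoters <- character(0)
    for (g in genes) {
      prom <- sample(bases, win, replace = TRUE)
      if (g %in% truth$module_genes && plant_rate > 0) {
        occupied <- rep(FALSE, win)
        for (pw in names(pwms)) {
          cons <- strsplit(pwm_consensus(pwms[[pw]]$counts), "")[[1]]
          m <- length(cons)
          k <- sample(seq_len(max(1, min(3, round(plant_rate + 1)))), 1)
          placed <- 0
          tries <- 0
          while (placed < k && tries < 200) {
            tries <- tries + 1
            p <- sample.int(win - m + 1L, 1)
            if (any(occupied[p:(p + m - 1)])) next
            prom[p:(p + m - 1)] <- cons
            occupied[p:(p + m - 1)] <- TRUE
            planted[[length(planted) + 1]] <- data.frame(
              gene = g, pwm = pw, pos = p, stringsAsFactors = FALSE)
            placed <- placed + 1
          }
        }
      }
      prom_str <- paste(prom, collapse = "")
      promoters[g] <- prom_str
      strand <- sample(c("+", "-"), 1)
      contig <- paste(sample(bases, 6001, replace = TRUE), collapse = "")
      tss0 <- 3000L # 0-based TSS position on the contig
      if (strand == "+") {
        # window [tss-3000, tss+1000] inclusive -> contig[1..4001] (1-based)
        substr(contig, tss0 - 3000 + 1, tss0 + 1000 + 1) <- prom_str
      } else {
        # transcript-oriented window maps to contig [tss-1000, tss+3000],
        # reverse-complemented
        substr(contig, tss0 - 1000 + 1, tss0 + 3000 + 1) <- revcomp(prom_str)
      }
      genome[[paste0("ctg_", g)]] <- contig
      tss_rows[[g]] <- data.frame(chrom = paste0("ctg_", g), tss = tss0,
                                  strand = strand, gene = g,
                                  stringsAsFactors = FALSE)
    }
    list(genome = unlist(genome), tss = do.call(rbind, tss_rows),
         promoters = promoters, pwms = pwms,
         planted = if (length(planted)) do.call(rbind, planted) else
           data.frame(gene = character(), pwm = character(), pos = integer()))
  })
}

#' Generate a synthetic siRNA growth screen over the module genes
#'
#' Two siRNAs per gene; a planted subset of growth-essential genes reduces
#' viability to ~55% of the negative control. Knockdown efficiency varies
#' so that most, but not all, genes exceed 50% mRNA reduction.
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` component of [generate_expression()].
#' @param n_growth_genes number of planted growth-essential genes.
#' @param seed optional RNG seed.
#' @return list with `wells` (sirna, gene, rep1..rep3), `control_wells`
#'   (numeric), `mrna` (sirna, gene, ratio, control_ratio) and
#'   `growth_genes` (the planted truth).
#' @export
generate_sirna_screen <- function(config, truth, n_growth_genes = 22,
                                  seed = sub_seed(config$seed, 80)) {
  genes <- truth$module_genes
  growth <- genes[seq_len(min(n_growth_genes, length(genes)))]
  with_seed(seed, {
    control_wells <- rnorm(6, 1000, 30)
    rows <- list()
    mrna <- list()
    for (g in genes) {
      for (j in 1:2) {
        sirna <- sprintf("%s_si%d", g, j)
        eff <- if (g %in% growth) rnorm(1, 0.55, 0.03) else rnorm(1, 1, 0.03)
        wells <- rnorm(3, 1000 * eff, 30)
        rows[[sirna]] <- data.frame(sirna = sirna, gene = g,
                                    rep1 = wells[1], rep2 = wells[2], rep3 = wells[3],
                                    stringsAsFactors = FALSE)
        kd <- if (runif(1) < 0.75) runif(1, 0.55, 0.9) else runif(1, 0.2, 0.5)
        mrna[[sirna]] <- data.frame(sirna = sirna, gene = g,
                                    ratio = (1 - kd), control_ratio = 1,
                                    stringsAsFactors = FALSE)
      }
    }
    list(wells = do.call(rbind, rows), control_wells = control_wells,
         mrna = do.call(rbind, mrna), growth_genes = growth)
  })
}
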