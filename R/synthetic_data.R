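# Synthetic cohort generator.  Every downstream stage (detection, CN
# signatures, covariates, immune scoring, survival) is exercised on data
# with a recorded ground truth: planted chromothripsis regions satisfy the
# clustering and oscillation criteria by construction, expression carries
# planted cell-type signature shifts, and survival times follow an
# exponential proportional-hazards model driven by the chromothripsis
# score.

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package's
#' tests: diploid genomes on the compact synthetic reference, half the
#' cohort carrying one planted chromothripsis event of 20 breakpoints
#' oscillating between two CN states within a 40 Mb region, sparse
#' background CNAs, a 2 log2-unit planted expression effect on cytotoxic
#' cell signatures, a per-CPS log hazard ratio of log(1.9) and 20%
#' independent censoring.
#'
#' @param n_samples cohort size.
#' @param chromothripsis_fraction fraction of samples with a planted event.
#' @param genome genome table (`chrom`, `length`, `arm_boundary`).
#' @param baseline_ploidy baseline integer copy number.
#' @param ct_region_length length (bp) of the planted shattered region.
#' @param ct_n_breakpoints breakpoints in the planted region (even, so the
#'   oscillation closes back to baseline at both flanks).
#' @param ct_cn_states number of distinct CN states in the planted region
#'   (>= 2; the default 2 gives an unambiguous regular oscillation).
#' @param background_breakpoint_rate background CNA events per Mb.
#' @param n_genes genes in the simulated expression matrix.
#' @param n_cell_signatures number of planted cell-type gene sets.
#' @param signature_genes_per_set genes per planted set.
#' @param signature_effect log2 shift applied to cytotoxic-set genes in
#'   samples WITHOUT chromothripsis (lower infiltration with chromothripsis).
#' @param hazard_log_hr_per_cps log hazard ratio per standardized CPS unit.
#' @param censoring_rate expected fraction of censored records.
#' @param response_base_rate responder probability at average CPS.
#' @param seed root seed; fixes every output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200,
                       chromothripsis_fraction = 0.5,
                       genome = synthetic_genome(),
                       baseline_ploidy = 2,
                       ct_region_length = 4e7,
                       ct_n_breakpoints = 20,
                       ct_cn_states = 2,
                       background_breakpoint_rate = 0.01,
                       n_genes = 2000,
                       n_cell_signatures = 28,
                       signature_genes_per_set = 10,
                       signature_effect = 2,
                       hazard_log_hr_per_cps = log(1.9),
                       censoring_rate = 0.2,
                       response_base_rate = 0.35,
                       seed = 1) {
  cfg <- list(n_samples = n_samples,
              chromothripsis_fraction = chromothripsis_fraction,
              genome = genome, baseline_ploidy = baseline_ploidy,
              ct_region_length = ct_region_length,
              ct_n_breakpoints = ct_n_breakpoints,
              ct_cn_states = ct_cn_states,
              background_breakpoint_rate = background_breakpoint_rate,
              n_genes = n_genes, n_cell_signatures = n_cell_signatures,
              signature_genes_per_set = signature_genes_per_set,
              signature_effect = signature_effect,
              hazard_log_hr_per_cps = hazard_log_hr_per_cps,
              censoring_rate = censoring_rate,
              response_base_rate = response_base_rate,
              seed = seed)
  stopifnot(n_samples >= 1, baseline_ploidy >= 1, n_genes >= 1,
            n_cell_signatures >= 1, signature_genes_per_set >= 1,
            ct_n_breakpoints >= 1, ct_cn_states >= 2,
            background_breakpoint_rate >= 0)
  if (chromothripsis_fraction < 0 || chromothripsis_fraction > 1)
    stop("chromothripsis_fraction must be in [0, 1]")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  if (ct_n_breakpoints %% 2 != 0)
    stop("ct_n_breakpoints must be even (oscillation must close to baseline)")
  autos <- genome[is_autosome(genome$chrom), , drop = FALSE]
  if (nrow(autos) == 0) stop("genome must contain at least one autosome")
  if (ct_region_length > min(autos$length))
    stop("ct_region_length exceeds the shortest autosome")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate one whole-genome copy-number profile
#'
#' Background CNAs are single-segment gains/losses of one copy with length
#' uniform on 1-10 Mb, arriving as a Poisson process along each chromosome.
#' With `has_ct`, one autosome carries a contiguous region of
#' `ct_n_breakpoints` breakpoints whose segments alternate deterministically
#' between the baseline and `ct_cn_states - 1` elevated CN levels, so the
#' clustering and oscillation criteria hold by construction.  Background
#' events overlapping the planted region are discarded.
#'
#' @param cfg a [sim_config()].
#' @param has_ct plant a chromothripsis event?
#' @param sample_id sample identifier.
#' @param seed seed for this profile (default derived from `cfg$seed`).
#' @return a [cn_profile] with attributes `has_ct`, `ct_chrom`, `ct_region`.
#' @export
simulate_cn_profile <- function(cfg, has_ct, sample_id = "S1",
                                seed = cfg$seed) {
  withr::with_seed(seed, {
    genome <- cfg$genome
    base <- cfg$baseline_ploidy
    ct_chrom <- NA_character_
    ct_region <- c(NA_real_, NA_real_)
    if (has_ct) {
      autos <- genome[is_autosome(genome$chrom) &
                        genome$length >= cfg$ct_region_length, , drop = FALSE]
      ct_chrom <- autos$chrom[sample.int(nrow(autos), 1)]
      clen <- autos$length[autos$chrom == ct_chrom]
      r_start <- floor(stats::runif(1, 1, clen - cfg$ct_region_length))
      ct_region <- c(r_start, r_start + cfg$ct_region_length - 1)
    }
    seg_list <- lapply(seq_len(nrow(genome)), function(gi) {
      chrom <- genome$chrom[gi]
      clen <- genome$length[gi]
      n_ev <- stats::rpois(1, cfg$background_breakpoint_rate * clen / 1e6)
      events <- list()
      if (n_ev > 0) {
        for (e in seq_len(n_ev)) {
          len <- round(stats::runif(1, 1e6, 1e7))
          s <- floor(stats::runif(1, 1, max(2, clen - len)))
          iv <- c(s, min(s + len - 1, clen))
          ok <- TRUE
          if (isTRUE(chrom == ct_chrom) &&
              iv[1] <= ct_region[2] && iv[2] >= ct_region[1]) ok <- FALSE
          for (prev in events)
            if (iv[1] <= prev$end && iv[2] >= prev$start) ok <- FALSE
          if (ok) {
            delta <- sample(c(-1L, 1L), 1)
            cn <- max(0L, base + delta)
            if (cn != base)
              events[[length(events) + 1L]] <-
                list(start = iv[1], end = iv[2], cn = cn)
          }
        }
      }
      bounds <- sort(unique(c(
        1, clen + 1,
        unlist(lapply(events, function(ev) c(ev$start, ev$end + 1)))
      )))
      starts <- bounds[-length(bounds)]
      ends <- bounds[-1] - 1
      cn <- rep(base, length(starts))
      for (ev in events) cn[starts == ev$start] <- ev$cn
      seg <- data.frame(chrom = chrom, start = starts, end = ends, cn = cn,
                        stringsAsFactors = FALSE)
      if (isTRUE(chrom == ct_chrom)) {
        seg <- subtract_regions(seg, data.frame(chrom = chrom,
                                                start = ct_region[1],
                                                end = ct_region[2]))
        n_bp <- cfg$ct_n_breakpoints
        bp_pos <- ct_region[1] +
          sort(sample.int(cfg$ct_region_length - 2L, n_bp))
        piece_start <- c(ct_region[1], bp_pos)
        piece_end <- c(bp_pos - 1, ct_region[2])
        up_levels <- base + seq_len(cfg$ct_cn_states - 1)
        cn_seq <- numeric(length(piece_start))
        up_idx <- 0L
        for (k in seq_along(cn_seq)) {
          if (k %% 2 == 1) {
            cn_seq[k] <- base
          } else {
            cn_seq[k] <- up_levels[(up_idx %% length(up_levels)) + 1L]
            up_idx <- up_idx + 1L
          }
        }
        seg <- rbind(seg, data.frame(chrom = chrom, start = piece_start,
                                     end = piece_end, cn = cn_seq,
                                     stringsAsFactors = FALSE))
        seg <- seg[order(seg$start), , drop = FALSE]
      }
      seg
    })
    seg <- merge_equal_segments(do.call(rbind, seg_list))
    out <- cn_profile(sample_id, seg, genome)
    attr(out, "has_ct") <- has_ct
    attr(out, "ct_chrom") <- ct_chrom
    attr(out, "ct_region") <- ct_region
    out
  })
}

#' Simulate a cohort of copy-number profiles with ground-truth labels
#'
#' @param cfg a [sim_config()].
#' @return list with `profiles` (named list of [cn_profile]) and `labels`
#'   (named logical vector, `TRUE` = planted chromothripsis).
#' @export
simulate_cohort_profiles <- function(cfg) {
  n <- cfg$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  n_ct <- round(n * cfg$chromothripsis_fraction)
  labels <- withr::with_seed(
    substream_seed(cfg$seed, 101),
    sample(c(rep(TRUE, n_ct), rep(FALSE, n - n_ct)))
  )
  names(labels) <- ids
  profiles <- lapply(seq_len(n), function(i) {
    simulate_cn_profile(cfg, labels[i], sample_id = ids[i],
                        seed = substream_seed(cfg$seed, 1000 + i))
  })
  names(profiles) <- ids
  list(profiles = profiles, labels = labels)
}

.nonsilent_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                        "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site")

#' Simulate a somatic mutation table (MAF-like)
#'
#' Per sample, nonsilent mutation counts are Poisson with mean
#' `nonsilent_rate * exome_size_mb`; silent mutations arrive at half that
#' rate and are flagged by `Variant_Classification = "Silent"`.  Population
#' frequencies are zero (somatic).
#'
#' @param cfg a [sim_config()].
#' @param nonsilent_rate nonsilent mutations per Mb.
#' @param exome_size_mb assayed coding territory in Mb.
#' @param sample_ids samples to simulate (default the cohort ids).
#' @param seed seed.
#' @return data.frame with MAF columns `Tumor_Sample_Barcode`,
#'   `Hugo_Symbol`, `Variant_Classification`, `Chromosome`,
#'   `Start_Position`, `allele_fraction`, `coverage`, `freq_1000G`.
#' @export
simulate_mutations <- function(cfg, nonsilent_rate, exome_size_mb = 30,
                               sample_ids = sprintf("S%04d", seq_len(cfg$n_samples)),
                               seed = substream_seed(cfg$seed, 201)) {
  stopifnot(nonsilent_rate >= 0, exome_size_mb > 0)
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    autos <- cfg$genome[is_autosome(cfg$genome$chrom), , drop = FALSE]
    rows <- lapply(sample_ids, function(sid) {
      n_ns <- stats::rpois(1, nonsilent_rate * exome_size_mb)
      n_sil <- stats::rpois(1, 0.5 * nonsilent_rate * exome_size_mb)
      n <- n_ns + n_sil
      if (n == 0) return(NULL)
      ci <- sample.int(nrow(autos), n, replace = TRUE)
      data.frame(
        Tumor_Sample_Barcode = sid,
        Hugo_Symbol = sample(genes, n, replace = TRUE),
        Variant_Classification = c(
          sample(.nonsilent_classes, n_ns, replace = TRUE),
          rep("Silent", n_sil)
        ),
        Chromosome = autos$chrom[ci],
        Start_Position = floor(stats::runif(n, 1, autos$length[ci])),
        allele_fraction = round(stats::runif(n, 0.05, 0.8), 4),
        coverage = stats::rpois(n, 80),
        freq_1000G = 0,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(Tumor_Sample_Barcode = character(),
                        Hugo_Symbol = character(),
                        Variant_Classification = character(),
                        Chromosome = character(), Start_Position = integer(),
                        allele_fraction = numeric(), coverage = integer(),
                        freq_1000G = numeric())
    rownames(out) <- NULL
    out
  })
}

#' Simulate a log2 expression matrix with planted immune gene sets
#'
#' Generates disjoint cell-type gene sets (the first five named CD8_T,
#' Treg, TAM, MDSC, NK), the eight cytokine-panel genes and CD8A/CD274 as
#' named genes, on a background of per-gene Gaussian log2 expression.
#' Genes of the cytotoxic sets (CD8_T, NK) and the proinflammatory
#' cytokines are shifted up by `signature_effect` in samples WITHOUT
#' chromothripsis, emulating reduced cytotoxic infiltration and a lower
#' pro/anti-inflammatory ratio with chromothripsis.
#'
#' @param cfg a [sim_config()].
#' @param labels named logical vector (TRUE = chromothripsis).
#' @param seed seed.
#' @return list with `expr` (genes x samples log2 matrix), `sets` (named
#'   list, GMT-compatible), `cytotoxic_sets` (names of the shifted sets).
#' @export
simulate_expression <- function(cfg, labels,
                                seed = substream_seed(cfg$seed, 301)) {
  n_set_genes <- cfg$n_cell_signatures * cfg$signature_genes_per_set
  special <- c("IFNG", "IL1A", "IL1B", "IL2", "IL4", "IL10", "IL11", "TGFB1",
               "CD8A", "CD274")
  if (cfg$n_genes < n_set_genes + length(special))
    stop("n_genes too small for the planted gene sets")
  withr::with_seed(seed, {
    n_bg <- cfg$n_genes - length(special)
    genes <- c(special, sprintf("G%04d", seq_len(n_bg)))
    set_names <- c("CD8_T", "Treg", "TAM", "MDSC", "NK",
                   sprintf("CellType_%02d", seq_len(max(0, cfg$n_cell_signatures - 5)) + 5))
    set_names <- set_names[seq_len(cfg$n_cell_signatures)]
    pool <- sprintf("G%04d", seq_len(n_set_genes))
    sets <- split(pool, rep(set_names, each = cfg$signature_genes_per_set))
    sets <- sets[set_names]
    cytotoxic <- intersect(c("CD8_T", "NK"), set_names)
    n <- length(labels)
    mu <- stats::rnorm(length(genes), mean = 5, sd = 1)
    expr <- matrix(stats::rnorm(length(genes) * n, mean = mu, sd = 1),
                   nrow = length(genes), ncol = n,
                   dimnames = list(genes, names(labels)))
    shifted <- unique(c(unlist(sets[cytotoxic]),
                        "IFNG", "IL1A", "IL1B", "IL2", "CD8A"))
    expr[shifted, !labels] <- expr[shifted, !labels] + cfg$signature_effect
    list(expr = expr, sets = sets, cytotoxic_sets = cytotoxic)
  })
}

#' Simulate survival and response data from chromothripsis scores
#'
#' Event times are exponential under a proportional-hazards model with
#' linear predictor `hazard_log_hr_per_cps * z`, where `z` is the
#' standardized score (or the raw score with `standardize = FALSE`, e.g.
#' for a binary group indicator).  Censoring is independent exponential
#' with its rate set so the expected censored fraction at baseline equals
#' `censoring_rate`.  The RECIST-like response label is drawn from a
#' logistic model decreasing in `z`, with its intercept set for a
#' `response_base_rate` responder rate at `z = 0`.
#'
#' @param cps named numeric vector of per-sample scores.
#' @param cfg a [sim_config()].
#' @param standardize standardize `cps` before use (default TRUE; requires
#'   non-constant scores).
#' @param seed seed.
#' @return data.frame `sample_id`, `os_time` (months), `os_event` (1 =
#'   death), `response` (CR/PR/SD/PD), `sd_duration` (months, SD rows).
#' @export
simulate_survival <- function(cps, cfg, standardize = TRUE,
                              seed = substream_seed(cfg$seed, 401)) {
  stopifnot(all(is.finite(cps)))
  z <- if (standardize) {
    if (stats::sd(cps) == 0) stop("cannot standardize constant scores")
    (cps - mean(cps)) / stats::sd(cps)
  } else cps
  withr::with_seed(seed, {
    n <- length(cps)
    lambda0 <- log(2) / 24  # 24-month baseline median survival
    rate <- lambda0 * exp(cfg$hazard_log_hr_per_cps * z)
    t_event <- stats::rexp(n, rate)
    if (cfg$censoring_rate >= 1) {
      os_time <- stats::rexp(n, lambda0)
      os_event <- rep(0L, n)
    } else if (cfg$censoring_rate <= 0) {
      os_time <- t_event
      os_event <- rep(1L, n)
    } else {
      lambda_c <- lambda0 * cfg$censoring_rate / (1 - cfg$censoring_rate)
      t_cens <- stats::rexp(n, lambda_c)
      os_time <- pmin(t_event, t_cens)
      os_event <- as.integer(t_event <= t_cens)
    }
    p_resp <- stats::plogis(stats::qlogis(cfg$response_base_rate) - z)
    resp <- stats::runif(n) < p_resp
    response <- character(n)
    sd_dur <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (resp[i]) {
        response[i] <- sample(c("CR", "PR", "SD"), 1, prob = c(0.2, 0.5, 0.3))
        if (response[i] == "SD") sd_dur[i] <- stats::runif(1, 6, 24)
      } else {
        response[i] <- sample(c("SD", "PD"), 1, prob = c(0.3, 0.7))
        if (response[i] == "SD") sd_dur[i] <- stats::runif(1, 0.5, 5.9)
      }
    }
    data.frame(sample_id = names(cps) %||% sprintf("S%04d", seq_len(n)),
               os_time = round(os_time, 3), os_event = os_event,
               response = response, sd_duration = round(sd_dur, 2),
               stringsAsFactors = FALSE)
  })
}
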