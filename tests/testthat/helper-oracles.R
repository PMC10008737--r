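# Fixture builders and independent brute-force oracles used across tests.

toy_genome <- function(lengths = c(chrA = 100e6, chrB = 100e6),
                       arm_frac = 0.5) {
  data.frame(chrom = names(lengths), length = unname(lengths),
             arm_boundary = unname(round(lengths * arm_frac)),
             stringsAsFactors = FALSE)
}

# Build a profile from a compact spec: list of (chrom, start, end, cn) rows.
toy_profile <- function(..., sample_id = "T1", genome = NULL) {
  rows <- list(...)
  seg <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), cn = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(genome)) {
    agg <- stats::aggregate(end ~ chrom, data = seg, FUN = max)
    genome <- toy_genome(stats::setNames(agg$end, agg$chrom))
  }
  cn_profile(sample_id, seg, genome)
}

# Per-base weighted-median ploidy oracle (only for small toy scales, bp
# coordinates scaled down so the multiset fits in memory).
ploidy_oracle <- function(p, scale = 1e6) {
  auto <- !grepl("(^|chr)[XY]$", p$segments$chrom)
  seg <- p$segments[auto, , drop = FALSE]
  reps <- unlist(mapply(function(cn, len) rep(cn, len), seg$cn,
                        (seg$end - seg$start + 1) / scale, SIMPLIFY = FALSE))
  reps <- sort(reps)
  n <- length(reps)
  # lower weighted median: smallest value with cumulative weight >= n/2
  reps[which(seq_len(n) >= n / 2)[1]]
}

# Independent ssGSEA running-sum oracle (naive double loop).
ssgsea_oracle <- function(expr, set, weight = 0.25, normalize = TRUE) {
  vapply(seq_len(ncol(expr)), function(s) {
    x <- expr[, s]
    genes <- rownames(expr)
    ord <- order(-x, genes)
    gl <- genes[ord]
    r <- rank(x, ties.method = "average")[ord]
    inset <- gl %in% set
    w <- abs(r)^weight
    sum_in <- sum(w[inset])
    n_out <- sum(!inset)
    running <- numeric(length(gl))
    acc_in <- 0; acc_out <- 0
    for (i in seq_along(gl)) {
      if (inset[i]) acc_in <- acc_in + w[i] / sum_in
      else acc_out <- acc_out + 1 / n_out
      running[i] <- acc_in - acc_out
    }
    es <- sum(running)
    if (normalize) {
      rng <- max(running) - min(running)
      es <- if (rng > 0) es / rng else 0
    }
    es
  }, numeric(1))
}

# Two-sided Fisher exact p by hypergeometric enumeration on a 2x2 table
# (a, b / c, d) with fixed margins.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Quadratic per-gene/per-segment overlap scan for CNA burden.
cna_burden_oracle <- function(p, genes, ploidy) {
  seg <- p$segments
  gain <- loss <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(seg))) {
      if (genes$chrom[i] != seg$chrom[j]) next
      if (genes$start[i] <= seg$end[j] && genes$end[i] >= seg$start[j]) {
        if (seg$cn[j] > ploidy) gain[i] <- TRUE
        if (seg$cn[j] < ploidy) loss[i] <- TRUE
      }
    }
  }
  c(gain = sum(gain), loss = sum(loss))
}

# Pairwise cumulative-case/dynamic-control AUC at time t, no censoring.
cd_auc_oracle <- function(time, marker, t0) {
  cases <- which(time <= t0)
  controls <- which(time > t0)
  if (!length(cases) || !length(controls)) return(NA_real_)
  tot <- 0
  for (i in cases) for (j in controls) {
    tot <- tot + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  }
  tot / (length(cases) * length(controls))
}

# Exhaustive scan for the longest two-state alternating run.
longest_chain_oracle <- function(cn) {
  m <- length(cn)
  best <- 1
  for (i in seq_len(m)) {
    for (j in i:m) {
      v <- cn[i:j]
      if (length(unique(v)) > 2) next
      if (length(v) >= 2 && any(v[-1] == v[-length(v)])) next
      best <- max(best, j - i + 1)
    }
  }
  best
}
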