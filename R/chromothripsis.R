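# Criteria-based chromothripsis calling on copy-number profiles.
#
# Two of the classical criteria are computable from integer-CN segments
# alone and drive the caller: (A) breakpoints cluster in a confined region,
# tested with a Monte-Carlo scan statistic against uniform placement, and
# (B) copy number oscillates regularly among few states.  Criteria that
# need SV orientation, haplotype or fragment-join data are structurally
# unavailable from CN-only input and are deliberately not emulated.

#' Scan-statistic test for breakpoint clustering on one chromosome
#'
#' Under the null that `n` breakpoints fall uniformly on the chromosome,
#' estimates the probability of observing at least the maximal window count
#' `k` in any window of width `window`, by Monte-Carlo simulation of the
#' scan statistic.  The maximizing window is reported.
#'
#' @param positions breakpoint positions (bp) on one chromosome.
#' @param chrom_length chromosome length (bp).
#' @param window scan window width in bp (default 50 Mb).
#' @param n_sim Monte-Carlo null draws (default 2000).
#' @param seed optional seed for the null draws.
#' @return list with `n`, `k` (max count in any window), `window_start`,
#'   `window_end`, `p_value`.  Fewer than 2 breakpoints yield `p_value = NA`
#'   (clustering undefined).
#' @export
breakpoint_cluster_test <- function(positions, chrom_length, window = 5e7,
                                    n_sim = 2000, seed = NULL) {
  n <- length(positions)
  if (n < 2) {
    return(list(n = n, k = n, window_start = NA_real_, window_end = NA_real_,
                p_value = NA_real_))
  }
  x <- sort(as.numeric(positions))
  counts <- findInterval(x + window, x) - seq_len(n) + 1L
  i_max <- which.max(counts)
  k_obs <- counts[i_max]
  draw <- function() {
    u <- sort(stats::runif(n, 0, chrom_length))
    max(findInterval(u + window, u) - seq_len(n) + 1L)
  }
  sim <- function() {
    hits <- 0L
    for (b in seq_len(n_sim)) if (draw() >= k_obs) hits <- hits + 1L
    hits
  }
  hits <- if (is.null(seed)) sim() else withr::with_seed(seed, sim())
  list(
    n = n, k = k_obs,
    window_start = x[i_max], window_end = x[i_max] + window,
    p_value = (1 + hits) / (n_sim + 1)
  )
}

#' Copy-number oscillation statistics for a run of segments
#'
#' @param cn ordered copy-number values of consecutive segments.
#' @return list with `n_cn_states` (distinct CN values),
#'   `oscillation_fraction` (fraction of interior segments whose CN differs
#'   from both neighbors while the neighbors share a value; `NA` when fewer
#'   than 3 segments), and `longest_oscillating_chain` (maximal run of
#'   segments alternating between exactly two CN states).
#' @export
oscillation_stats <- function(cn) {
  m <- length(cn)
  n_states <- length(unique(cn))
  if (m < 3) {
    return(list(n_cn_states = n_states, oscillation_fraction = NA_real_,
                longest_oscillating_chain = m))
  }
  interior <- 2:(m - 1)
  osc <- (cn[interior] != cn[interior - 1]) &
    (cn[interior] != cn[interior + 1]) &
    (cn[interior - 1] == cn[interior + 1])
  chains <- oscillating_runs(cn)
  list(
    n_cn_states = n_states,
    oscillation_fraction = mean(osc),
    longest_oscillating_chain = max(chains)
  )
}

# Lengths of all maximal runs alternating between exactly two CN states.
# Consecutive maximal runs share their boundary element.
oscillating_runs <- function(cn) {
  m <- length(cn)
  if (m < 2) return(m)
  lens <- integer(0)
  i <- 1L
  while (i < m) {
    if (cn[i + 1] == cn[i]) {
      i <- i + 1L
      next
    }
    j <- i + 1L
    while (j < m && cn[j + 1] != cn[j] && cn[j + 1] == cn[j - 1]) j <- j + 1L
    lens <- c(lens, j - i + 1L)
    i <- j
  }
  if (!length(lens)) 1L else lens
}

#' Default thresholds for the chromothripsis caller
#'
#' @param window scan window width (bp).
#' @param alpha significance level for the clustering test.
#' @param min_breakpoints minimum breakpoints in the densest window.
#' @param max_states maximum distinct CN states in the candidate region.
#' @param min_osc minimum oscillation fraction in the candidate region.
#' @param n_sim Monte-Carlo draws for the clustering test.
#' @return named list of thresholds.
#' @export
ct_thresholds <- function(window = 5e7, alpha = 0.05, min_breakpoints = 10,
                          max_states = 3, min_osc = 0.5, n_sim = 2000) {
  list(window = window, alpha = alpha, min_breakpoints = min_breakpoints,
       max_states = max_states, min_osc = min_osc, n_sim = n_sim)
}

#' Call chromothripsis on a copy-number profile
#'
#' Per chromosome: finds the densest breakpoint window; when it holds at
#' least `min_breakpoints` breakpoints, tests clustering by Monte-Carlo scan
#' statistic and computes oscillation statistics over the segments
#' intersecting the window.  A chromosome is flagged when the window count,
#' cluster p-value, number of CN states and oscillation fraction all pass
#' their thresholds; the sample is flagged when any chromosome is.  The
#' clustering p-value is only computed for chromosomes that reach the
#' breakpoint minimum (it cannot change the call elsewhere).
#'
#' @param p a filtered [cn_profile] (a retained X chromosome triggers a
#'   warning but calling proceeds).
#' @param thresholds list from [ct_thresholds()].
#' @param seed seed for the Monte-Carlo clustering tests.
#' @return data.frame of per-chromosome calls (`sample_id`, `chrom`,
#'   `region_start`, `region_end`, `n_breakpoints`, `n_cn_states`,
#'   `oscillation_fraction`, `cluster_pvalue`, `is_chromothripsis`) with
#'   attribute `sample_flag` (logical).
#' @export
call_chromothripsis <- function(p, thresholds = ct_thresholds(), seed = 1) {
  if (any(p$segments$chrom %in% c("chrX", "X")))
    warning("profile contains chrX; expected a filtered profile")
  bp <- breakpoints(p)
  chroms <- unique(p$segments$chrom)
  calls <- lapply(seq_along(chroms), function(ci) {
    chrom <- chroms[ci]
    cb <- bp[bp$chrom == chrom, , drop = FALSE]
    clen <- p$genome$length[match(chrom, p$genome$chrom)]
    if (is.na(clen)) clen <- max(p$segments$end[p$segments$chrom == chrom])
    row <- data.frame(
      sample_id = p$sample_id, chrom = chrom,
      region_start = NA_real_, region_end = NA_real_,
      n_breakpoints = nrow(cb), n_cn_states = NA_integer_,
      oscillation_fraction = NA_real_, cluster_pvalue = NA_real_,
      is_chromothripsis = FALSE, stringsAsFactors = FALSE
    )
    if (nrow(cb) < 2) return(row)
    scan <- breakpoint_cluster_test(
      cb$position, clen, window = thresholds$window,
      n_sim = if (nrow(cb) >= thresholds$min_breakpoints) thresholds$n_sim else 0,
      seed = substream_seed(seed, ci)
    )
    if (nrow(cb) < thresholds$min_breakpoints) scan$p_value <- NA_real_
    row$region_start <- scan$window_start
    row$region_end <- scan$window_end
    seg <- p$segments[p$segments$chrom == chrom, , drop = FALSE]
    in_win <- seg$end >= scan$window_start & seg$start <= scan$window_end
    osc <- oscillation_stats(seg$cn[in_win])
    row$n_cn_states <- osc$n_cn_states
    row$oscillation_fraction <- osc$oscillation_fraction
    row$cluster_pvalue <- scan$p_value
    row$is_chromothripsis <-
      scan$k >= thresholds$min_breakpoints &&
      !is.na(scan$p_value) && scan$p_value <= thresholds$alpha &&
      osc$n_cn_states <= thresholds$max_states &&
      !is.na(osc$oscillation_fraction) &&
      osc$oscillation_fraction >= thresholds$min_osc
    row
  })
  out <- do.call(rbind, calls)
  attr(out, "sample_flag") <- any(out$is_chromothripsis)
  attr(out, "thresholds") <- thresholds
  out
}
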