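# Per-sample genomic covariates: MAF variant filtering, tumor mutational
# burden, key-gene mutation frequencies with Fisher tests, copy-number
# alteration burden by gene-interval overlap, and the weighted genome
# instability index.

#' Filter a somatic mutation table
#'
#' Keeps records passing all three rules: confidence (coverage >= 5 OR
#' allele fraction > 0.05 -- the disjunction is deliberate and documented),
#' nonsilent classification (missense, nonsense, frameshift, splice site),
#' and rarity (every provided population-frequency column, matched by the
#' `freq_` prefix, below 0.005).  When no population-frequency column is
#' present the rarity rule is skipped with a warning.  Idempotent.
#'
#' @param maf data.frame with MAF-style columns `Variant_Classification`
#'   plus `coverage` and `allele_fraction`; population frequencies in
#'   columns named `freq_*`.
#' @param min_coverage,min_vaf confidence thresholds.
#' @param max_pop_freq rarity threshold.
#' @param nonsilent_classes classifications counted as nonsilent.
#' @return filtered data.frame.
#' @export
filter_variants <- function(maf, min_coverage = 5, min_vaf = 0.05,
                            max_pop_freq = 0.005,
                            nonsilent_classes = .nonsilent_classes) {
  stopifnot(all(c("Variant_Classification", "coverage", "allele_fraction")
                %in% names(maf)))
  keep <- (maf$coverage >= min_coverage | maf$allele_fraction > min_vaf) &
    maf$Variant_Classification %in% nonsilent_classes
  freq_cols <- grep("^freq_", names(maf), value = TRUE)
  if (!length(freq_cols)) {
    warning("no population-frequency columns (freq_*); rarity rule skipped")
  } else {
    for (fc in freq_cols) keep <- keep & maf[[fc]] < max_pop_freq
  }
  out <- maf[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden per sample
#'
#' Qualifying mutations per megabase of assayed territory.  Pass the table
#' through [filter_variants()] first to count only rare nonsilent variants.
#'
#' @param maf mutation table with `Tumor_Sample_Barcode`.
#' @param region_size_mb assayed territory in Mb (default 30).
#' @param sample_ids samples to report (defaults to those present; samples
#'   without records get TMB 0).
#' @return named numeric vector of mutations/Mb.
#' @export
compute_tmb <- function(maf, region_size_mb = 30, sample_ids = NULL) {
  if (region_size_mb <= 0) stop("region_size_mb must be positive")
  counts <- table(maf$Tumor_Sample_Barcode)
  if (is.null(sample_ids)) sample_ids <- names(counts)
  tmb <- stats::setNames(rep(0, length(sample_ids)), sample_ids)
  present <- intersect(sample_ids, names(counts))
  tmb[present] <- as.numeric(counts[present])
  tmb / region_size_mb
}

#' Key-gene mutation frequency by group with Fisher exact tests
#'
#' For each gene, the fraction of samples per group carrying at least one
#' qualifying mutation, and the two-sided Fisher exact p-value of the
#' 2x2 (group x mutated) table.  Benjamini-Hochberg q-values across the
#' panel are also reported.
#'
#' @param maf filtered mutation table.
#' @param genes character vector of gene symbols.
#' @param groups named logical vector, sample -> group flag (must cover all
#'   samples of interest; samples absent from `maf` count as unmutated).
#' @return data.frame with per-group frequencies, counts, `p_value`,
#'   `q_value`, and `present` (gene seen in the table at all).
#' @export
mutation_frequency_by_group <- function(maf, genes, groups) {
  stopifnot(is.logical(groups), !is.null(names(groups)))
  if (!length(genes))
    return(data.frame(gene = character(), freq_true = numeric(),
                      freq_false = numeric(), p_value = numeric(),
                      q_value = numeric(), present = logical()))
  n1 <- sum(groups)
  n0 <- sum(!groups)
  rows <- lapply(genes, function(g) {
    mut_samples <- unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == g])
    mut <- names(groups) %in% mut_samples
    a <- sum(mut & groups); b <- sum(mut & !groups)
    p <- stats::fisher.test(matrix(c(a, n1 - a, b, n0 - b), 2))$p.value
    data.frame(gene = g, freq_true = a / n1, freq_false = b / n0,
               n_true = a, n_false = b, p_value = p,
               present = g %in% maf$Hugo_Symbol, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Copy-number alteration burden: genes gained and lost
#'
#' A gene counts as gained (lost) when it overlaps by at least one base any
#' segment with CN above (below) the ploidy; each gene counts at most once
#' per direction.
#'
#' @param p a [cn_profile].
#' @param genes data.frame with `chrom`, `start`, `end`, `gene` (1-based
#'   inclusive intervals on the profile's genome).
#' @param ploidy baseline integer ploidy; [tumor_ploidy()] when `NULL`.
#' @return named numeric vector `c(gain = , loss = )`.
#' @export
cna_burden <- function(p, genes, ploidy = NULL) {
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
  if (is.null(ploidy)) ploidy <- tumor_ploidy(p)
  seg <- p$segments
  count_dir <- function(cond) {
    s <- seg[cond, , drop = FALSE]
    if (nrow(s) == 0) return(0L)
    hit <- logical(nrow(genes))
    for (chrom in unique(s$chrom)) {
      gi <- which(genes$chrom == chrom)
      if (!length(gi)) next
      q <- IRanges::IRanges(genes$start[gi], genes$end[gi])
      subj <- IRanges::IRanges(s$start[s$chrom == chrom],
                               s$end[s$chrom == chrom])
      ov <- IRanges::overlapsAny(q, subj)
      hit[gi] <- hit[gi] | ov
    }
    sum(hit)
  }
  c(gain = count_dir(seg$cn > ploidy), loss = count_dir(seg$cn < ploidy))
}

#' Weighted genome instability index (wGII)
#'
#' Per autosome with coverage, the fraction of covered bases whose copy
#' number differs from the tumor ploidy; wGII is the unweighted mean of
#' these fractions over covered autosomes.  Always in \[0, 1\].
#'
#' @param p a [cn_profile].
#' @param ploidy baseline integer ploidy; [tumor_ploidy()] when `NULL`.
#' @return wGII.
#' @export
compute_wgii <- function(p, ploidy = NULL) {
  seg <- p$segments[is_autosome(p$segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0) stop("wGII undefined: no autosomal coverage")
  if (is.null(ploidy)) ploidy <- tumor_ploidy(p)
  len <- seg$end - seg$start + 1
  altered <- seg$cn != ploidy
  frac <- vapply(split(seq_len(nrow(seg)), seg$chrom), function(i) {
    sum(len[i][altered[i]]) / sum(len[i])
  }, numeric(1))
  mean(frac)
}
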