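# Expression-based microenvironment quantification: single-sample gene-set
# enrichment (ssGSEA), geometric-mean signature scores (which, unlike
# ssGSEA scores, are strictly positive and therefore ratio-safe),
# cell-type and cytokine ratios, and two-group pathway differentials.

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending; ties broken by
#' gene name for determinism).  The running statistic is the difference
#' between the weighted in-set ECDF (weights `|rank statistic|^weight`,
#' where the rank statistic of a gene is its expression rank, N = highest)
#' and the unweighted out-of-set ECDF; the enrichment score is the sum of
#' the running statistic over the list, optionally normalized by the range
#' (max - min) of the running statistic so scores are comparable across
#' samples.
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param sets named list of gene-symbol vectors.
#' @param weight rank-weight exponent (default 0.25).
#' @param normalize divide by the running-statistic range (default TRUE).
#' @return sets x samples score matrix (attribute `method = "ssgsea"`).
#'   Sets with no genes in the matrix get `NA` rows and a warning.
#' @export
ssgsea <- function(expr, sets, weight = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2, !is.null(rownames(expr)))
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  genes <- rownames(expr)
  overlap <- lapply(sets, intersect, x = genes)
  empty <- names(sets)[vapply(overlap, length, 1L) == 0]
  if (length(empty))
    warning("set(s) with no overlapping genes: ", paste(empty, collapse = ", "))
  N <- length(genes)
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    ord <- order(-x, genes)
    stat <- rank(x, ties.method = "average")[ord]  # ~N..1 down the list
    stat <- abs(stat)^weight
    for (k in seq_along(sets)) {
      gs <- overlap[[names(sets)[k]]]
      if (!length(gs)) next
      inset <- genes[ord] %in% gs
      n_out <- N - sum(inset)
      p_in <- cumsum(stat * inset) / sum(stat[inset])
      p_out <- if (n_out > 0) cumsum(!inset) / n_out else numeric(N)
      running <- p_in - p_out
      es <- sum(running)
      if (normalize) {
        rng <- max(running) - min(running)
        es <- if (rng > 0) es / rng else 0
      }
      scores[k, s] <- es
    }
  }
  attr(scores, "method") <- "ssgsea"
  scores
}

#' Geometric-mean gene-set scores
#'
#' Score of a set in a sample = geometric mean of `value + pseudocount`
#' over the set's genes present in the matrix.  Expression must be on
#' linear scale, or declared log2 (`expr_scale = "log2"`) to be
#' exponentiated internally.
#'
#' @param expr genes x samples matrix.
#' @param sets named list of gene sets.
#' @param pseudocount added before the log (default 1).
#' @param expr_scale `"linear"` or `"log2"`.
#' @return sets x samples matrix (attribute `method = "geometric_mean"`).
#' @export
geometric_mean_scores <- function(expr, sets, pseudocount = 1,
                                  expr_scale = c("linear", "log2")) {
  expr_scale <- match.arg(expr_scale)
  stopifnot(pseudocount >= 0)
  if (expr_scale == "log2") expr <- 2^expr
  genes <- rownames(expr)
  scores <- matrix(NA_real_, length(sets), ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  for (k in seq_along(sets)) {
    gs <- intersect(sets[[k]], genes)
    if (!length(gs)) {
      warning("set ", names(sets)[k], " has no overlapping genes")
      next
    }
    v <- expr[gs, , drop = FALSE] + pseudocount
    if (any(v <= 0)) {
      bad <- which(v <= 0, arr.ind = TRUE)[1, ]
      stop("non-positive value for gene ", gs[bad[1]], ", sample ",
           colnames(expr)[bad[2]])
    }
    scores[k, ] <- exp(colMeans(log(v)))
  }
  attr(scores, "method") <- "geometric_mean"
  scores
}

#' CD8 T-cell ratios to immunosuppressive populations
#'
#' Elementwise quotients of geometric-mean score rows: CD8/Treg, CD8/TAM
#' and CD8/MDSC, reported raw and on log2 scale.  Geometric-mean scores are
#' required because ssGSEA scores can be negative, which breaks ratios.
#'
#' @param scores sets x samples matrix from [geometric_mean_scores()].
#' @param cd8,treg,tam,mdsc row names of the four populations.
#' @return data.frame per sample with raw and log2 ratios; zero
#'   denominators yield `NA`.
#' @export
cell_ratios <- function(scores, cd8 = "CD8_T", treg = "Treg", tam = "TAM",
                        mdsc = "MDSC") {
  if (!identical(attr(scores, "method"), "geometric_mean"))
    warning("cell_ratios expects geometric-mean scores (ssGSEA can be negative)")
  need <- c(cd8, treg, tam, mdsc)
  missing <- setdiff(need, rownames(scores))
  if (length(missing)) stop("missing score rows: ", paste(missing, collapse = ", "))
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  out <- data.frame(
    sample_id = colnames(scores),
    cd8_treg = safe_div(scores[cd8, ], scores[treg, ]),
    cd8_tam = safe_div(scores[cd8, ], scores[tam, ]),
    cd8_mdsc = safe_div(scores[cd8, ], scores[mdsc, ]),
    stringsAsFactors = FALSE
  )
  out$log2_cd8_treg <- log2(out$cd8_treg)
  out$log2_cd8_tam <- log2(out$cd8_tam)
  out$log2_cd8_mdsc <- log2(out$cd8_mdsc)
  rownames(out) <- NULL
  out
}

#' Pro- to anti-inflammatory cytokine expression ratio
#'
#' `log2(geometric_mean(pro) / geometric_mean(anti))` per sample.  Default
#' panels: IFNG, IL1A, IL1B, IL2 (proinflammatory) versus IL4, IL10, IL11,
#' TGFB1 (immunosuppressive).  Panel genes absent from the matrix are
#' dropped with a warning.
#'
#' @param expr genes x samples matrix.
#' @param pro,anti cytokine panels.
#' @param pseudocount,expr_scale passed to [geometric_mean_scores()].
#' @return named numeric vector of per-sample log2 ratios.
#' @export
cytokine_ratio <- function(expr, pro = c("IFNG", "IL1A", "IL1B", "IL2"),
                           anti = c("IL4", "IL10", "IL11", "TGFB1"),
                           pseudocount = 1,
                           expr_scale = c("linear", "log2")) {
  expr_scale <- match.arg(expr_scale)
  for (panel in list(pro, anti)) {
    absent <- setdiff(panel, rownames(expr))
    if (length(absent))
      warning("panel gene(s) absent, computed on intersection: ",
              paste(absent, collapse = ", "))
  }
  sc <- geometric_mean_scores(expr, list(pro = pro, anti = anti),
                              pseudocount = pseudocount,
                              expr_scale = expr_scale)
  stats::setNames(log2(sc["pro", ] / sc["anti", ]), colnames(expr))
}

#' Two-group differential of gene-set scores
#'
#' Welch two-sample t statistic per score row, signed so that positive
#' means higher in the `FALSE` (non-chromothripsis) group, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param scores sets x samples matrix.
#' @param groups logical vector per sample (TRUE = chromothripsis).
#' @return data.frame with `set`, `t`, `p_value`, `q_value`, `flagged`
#'   (zero variance in both groups).
#' @export
pathway_differential <- function(scores, groups) {
  stopifnot(ncol(scores) == length(groups), is.logical(groups))
  if (sum(groups) < 2 || sum(!groups) < 2)
    stop("both groups need at least 2 samples")
  rows <- lapply(rownames(scores), function(nm) {
    a <- scores[nm, !groups]  # non-chromothripsis
    b <- scores[nm, groups]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(set = nm, t = NA_real_, p_value = NA_real_,
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b)
    data.frame(set = nm, t = unname(tt$statistic), p_value = tt$p.value,
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Total immune infiltration score
#'
#' Summary of the per-sample infiltration across all cell-type sets; the
#' mean of the per-set scores by default (configurable to the sum).
#'
#' @param scores sets x samples matrix.
#' @param method `"mean"` or `"sum"`.
#' @return named numeric vector per sample.
#' @export
total_infiltration_score <- function(scores, method = c("mean", "sum")) {
  method <- match.arg(method)
  f <- if (method == "mean") colMeans else colSums
  f(scores)
}
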