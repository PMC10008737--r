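#' @keywords internal
#' @importFrom mclust Mclust mclustBIC
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve of `scores` for discriminating `labels == TRUE`
#' from `labels == FALSE`, computed from ranks (equivalent to the normalized
#' Wilcoxon statistic; ties contribute 1/2).
#'
#' @param scores numeric vector.
#' @param labels logical vector of the same length.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Deterministic per-stage seed derived from a root seed; stays < 2^31.
substream_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2147483629) * 48271 + as.numeric(k)) %% 2147483629
}

geom_mean <- function(x) exp(mean(log(x)))

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match extracted factors to reference factors by cosine similarity
#'
#' Finds the column permutation of `extracted` maximizing the mean cosine
#' similarity with the columns of `reference` (exhaustive over permutations;
#' intended for small factor counts).
#'
#' @param reference,extracted matrices with the same number of columns.
#' @return list with `perm` (permutation of extracted columns) and
#'   `cosines` (per-reference-column similarity under that permutation).
#' @export
match_signatures <- function(reference, extracted) {
  K <- ncol(reference)
  stopifnot(ncol(extracted) == K, K <= 7)
  sim <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    sim[i, j] <- cosine_similarity(reference[, i], extracted[, j])
  perms <- permutations_of(K)
  best <- NULL
  best_val <- -Inf
  for (p in perms) {
    v <- mean(sim[cbind(seq_len(K), p)])
    if (v > best_val) {
      best_val <- v
      best <- p
    }
  }
  list(perm = best, cosines = sim[cbind(seq_len(K), best)])
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, then member genes, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
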