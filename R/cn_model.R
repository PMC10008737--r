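# Copy-number data model: integer-CN segment profiles, SEG I/O, the
# short-change/immunoglobulin-locus filter, ploidy and breakpoints.

#' Synthetic reference genome used by the simulator and examples
#'
#' A compact genome of eight autosomes plus chrX.  Coordinates are 1-based
#' inclusive throughout the package (SEG convention).  `arm_boundary` is the
#' last base of the p arm.
#'
#' @return data.frame with columns `chrom`, `length`, `arm_boundary`.
#' @export
synthetic_genome <- function() {
  data.frame(
    chrom = c(paste0("chr", 1:8), "chrX"),
    length = c(200, 180, 160, 140, 120, 100, 90, 80, 150) * 1e6,
    arm_boundary = c(100, 90, 80, 70, 60, 50, 45, 40, 60) * 1e6,
    stringsAsFactors = FALSE
  )
}

is_autosome <- function(chrom) !grepl("(^|chr)[XY]$", chrom)

#' Construct a copy-number profile
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`, `cn`
#'   (1-based inclusive coordinates, non-negative integer copy number).
#' @param genome data.frame of chromosome `chrom`, `length`, `arm_boundary`;
#'   defaults to [synthetic_genome()].
#' @return object of class `cn_profile`.
#' @export
cn_profile <- function(sample_id, segments, genome = synthetic_genome()) {
  stopifnot(all(c("chrom", "start", "end", "cn") %in% names(segments)))
  segments <- segments[, c("chrom", "start", "end", "cn")]
  segments$chrom <- as.character(segments$chrom)
  o <- order(match(segments$chrom, unique(segments$chrom)), segments$start)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  if (nrow(segments)) {
    if (any(segments$start > segments$end))
      stop("segment start > end for sample ", sample_id)
    if (any(segments$cn < 0) || any(segments$cn != round(segments$cn)))
      stop("copy numbers must be non-negative integers")
    by_chr <- split(segments, segments$chrom)
    for (s in by_chr) {
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stop("overlapping segments on ", s$chrom[1], " for sample ", sample_id)
    }
  }
  structure(
    list(sample_id = sample_id, segments = segments, genome = genome),
    class = "cn_profile"
  )
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile>", x$sample_id, "-", nrow(x$segments), "segments on",
      length(unique(x$segments$chrom)), "chromosomes\n")
  invisible(x)
}

#' Read a SEG file into copy-number profiles
#'
#' Expects a tab-delimited file with header columns `sample`, `chrom`,
#' `start`, `end`, `cn` (1-based inclusive, integer copy number).  Malformed
#' rows raise an error naming the offending file line.
#'
#' @param path SEG file path.
#' @param genome optional genome table; inferred from the data when `NULL`
#'   (length = max end seen, arm boundary = midpoint).
#' @return named list of [cn_profile] objects.
#' @export
read_seg <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample", "chrom", "start", "end", "cn")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("SEG file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(d) == 0) return(list())
  line_no <- seq_len(nrow(d)) + 1L  # header is line 1
  for (col in c("start", "end", "cn")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      stop("non-integer ", col, " at line ", line_no[bad[1]], " of ", path)
    d[[col]] <- as.integer(round(v))
  }
  bad <- which(d$start > d$end)
  if (length(bad))
    stop("start > end at line ", line_no[bad[1]], " of ", path)
  bad <- which(d$cn < 0)
  if (length(bad))
    stop("negative copy number at line ", line_no[bad[1]], " of ", path)
  if (is.null(genome)) {
    agg <- stats::aggregate(end ~ chrom, data = d, FUN = max)
    genome <- data.frame(chrom = agg$chrom, length = agg$end,
                         arm_boundary = round(agg$end / 2),
                         stringsAsFactors = FALSE)
  }
  profiles <- lapply(split(d, d$sample), function(s) {
    cn_profile(s$sample[1], s[, c("chrom", "start", "end", "cn")], genome)
  })
  profiles[unique(d$sample)]
}

#' Write copy-number profiles to a SEG file
#'
#' @param profiles list of [cn_profile] objects (or a single profile).
#' @param path output path.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$segments) == 0) return(NULL)
    cbind(sample = p$sample_id, p$segments)
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(sample = character(), chrom = character(),
                    start = integer(), end = integer(), cn = integer())
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Merge contiguous equal-CN segments (end + 1 == next start) per chromosome.
merge_equal_segments <- function(segments) {
  if (nrow(segments) < 2) return(segments)
  out <- do.call(rbind, lapply(split(segments, segments$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    keep <- 1L
    for (i in seq_len(nrow(s))[-1]) {
      j <- keep[length(keep)]
      if (s$cn[i] == s$cn[j] && s$start[i] == s$end[j] + 1L) {
        s$end[j] <- s$end[i]
      } else {
        keep <- c(keep, i)
      }
    }
    s[keep, , drop = FALSE]
  }))
  out <- out[order(match(out$chrom, unique(segments$chrom)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-weighted median integer copy number (tumor ploidy)
#'
#' Weighted median of segment copy numbers over autosomes, weights equal to
#' segment lengths.  When the cumulative weight reaches exactly half the
#' total the lower of the two straddling values is returned (deterministic,
#' conservative tie rule).
#'
#' @param p a [cn_profile].
#' @return integer ploidy.
#' @export
tumor_ploidy <- function(p) {
  seg <- p$segments[is_autosome(p$segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0) stop("ploidy undefined: no autosomal segments")
  w <- stats::aggregate(len ~ cn,
                        data = data.frame(cn = seg$cn,
                                          len = seg$end - seg$start + 1),
                        FUN = sum)
  w <- w[order(w$cn), ]
  cum <- cumsum(w$len)
  total <- cum[length(cum)]
  as.integer(w$cn[which(cum >= total / 2)[1]])
}

#' Breakpoints of a copy-number profile
#'
#' One breakpoint per pair of consecutive same-chromosome segments with
#' differing copy number; chromosome ends are not breakpoints.  The reported
#' position is the last base of the left segment.
#'
#' @param p a [cn_profile].
#' @return data.frame with `chrom`, `position`, `left_cn`, `right_cn`.
#' @export
breakpoints <- function(p) {
  seg <- p$segments
  empty <- data.frame(chrom = character(), position = integer(),
                      left_cn = integer(), right_cn = integer())
  if (nrow(seg) < 2) return(empty)
  out <- lapply(split(seg, seg$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2) return(NULL)
    i <- which(diff(s$cn) != 0)
    if (!length(i)) return(NULL)
    data.frame(chrom = s$chrom[i], position = s$end[i],
               left_cn = s$cn[i], right_cn = s$cn[i + 1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(match(out$chrom, unique(seg$chrom)), out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default immunoglobulin-locus exclusion intervals (GRCh38, approximate)
#'
#' IGH (14q32), IGK (2p11) and IGL (22q11) loci, 1-based inclusive.  Only
#' relevant for real GRCh38 data; the synthetic genome uses different
#' chromosome names and is unaffected.
#'
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
ig_exclusion_regions <- function() {
  data.frame(
    chrom = c("chr14", "chr2", "chr22"),
    start = c(105586437L, 88857361L, 22026076L),
    end = c(106879844L, 90235368L, 22922913L),
    stringsAsFactors = FALSE
  )
}

subtract_regions <- function(segments, regions) {
  if (nrow(segments) == 0 || is.null(regions) || nrow(regions) == 0)
    return(segments)
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    cur <- data.frame(start = s$start, end = s$end)
    hits <- regions[regions$chrom == s$chrom, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      nxt <- list()
      for (k in seq_len(nrow(cur))) {
        a <- cur$start[k]; b <- cur$end[k]
        if (hits$end[j] < a || hits$start[j] > b) {
          nxt[[length(nxt) + 1L]] <- c(a, b)
        } else {
          if (a < hits$start[j]) nxt[[length(nxt) + 1L]] <- c(a, hits$start[j] - 1L)
          if (b > hits$end[j]) nxt[[length(nxt) + 1L]] <- c(hits$end[j] + 1L, b)
        }
      }
      cur <- if (length(nxt)) {
        m <- do.call(rbind, nxt)
        data.frame(start = m[, 1], end = m[, 2])
      } else data.frame(start = integer(), end = integer())
      if (nrow(cur) == 0) break
    }
    if (nrow(cur))
      pieces[[length(pieces) + 1L]] <-
        data.frame(chrom = s$chrom, start = cur$start, end = cur$end, cn = s$cn)
  }
  if (!length(pieces))
    return(segments[0, , drop = FALSE])
  out <- do.call(rbind, pieces)
  out[order(match(out$chrom, unique(segments$chrom)), out$start), , drop = FALSE]
}

#' Preprocess a copy-number profile
#'
#' Drops the X chromosome and any user-supplied exclusion intervals
#' (immunoglobulin loci on real data), then removes copy-number changes
#' shorter than `min_change_len`: a segment whose CN differs from the sample
#' baseline ploidy and whose length is below the threshold is reverted to
#' the flanking state, and equal contiguous neighbors are merged.  Ploidy is
#' the length-weighted median computed on the unfiltered profile (or passed
#' explicitly).  Reversion and merging are iterated to a fixed point, so the
#' operation is idempotent.
#'
#' @param p a [cn_profile].
#' @param min_change_len minimum length (bp) of a retained CN change;
#'   default 50 kb.
#' @param excluded_regions optional data.frame `chrom`,`start`,`end`
#'   (1-based inclusive) to subtract, e.g. [ig_exclusion_regions()].
#' @param drop_chroms chromosomes removed outright (default chrX/X/chrY/Y).
#' @param ploidy baseline integer ploidy; computed from `p` when `NULL`.
#' @return filtered [cn_profile].
#' @export
filter_profile <- function(p, min_change_len = 5e4, excluded_regions = NULL,
                           drop_chroms = c("chrX", "X", "chrY", "Y"),
                           ploidy = NULL) {
  seg <- p$segments
  if (is.null(ploidy)) {
    ploidy <- if (any(is_autosome(seg$chrom))) tumor_ploidy(p) else NA_integer_
  }
  seg <- seg[!(seg$chrom %in% drop_chroms), , drop = FALSE]
  seg <- subtract_regions(seg, excluded_regions)
  if (!is.na(ploidy) && nrow(seg)) {
    repeat {
      seg <- merge_equal_segments(seg)
      len <- seg$end - seg$start + 1
      short <- which(seg$cn != ploidy & len < min_change_len)
      if (!length(short)) break
      for (i in short) {
        # revert to a contiguous flank so the subsequent merge removes the
        # breakpoints; an isolated changed segment reverts to ploidy
        left_ok <- i > 1 && seg$chrom[i - 1] == seg$chrom[i] &&
          seg$end[i - 1] + 1L == seg$start[i]
        right_ok <- i < nrow(seg) && seg$chrom[i + 1] == seg$chrom[i] &&
          seg$start[i + 1] == seg$end[i] + 1L
        seg$cn[i] <- if (left_ok) seg$cn[i - 1]
                     else if (right_ok) seg$cn[i + 1]
                     else ploidy
      }
    }
  }
  rownames(seg) <- NULL
  out <- cn_profile(p$sample_id, seg, p$genome)
  attr(out, "ploidy") <- ploidy
  out
}
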