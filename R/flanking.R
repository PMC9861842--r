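## Flanking-intron characterization: repeat content, weighted DNA
## methylation, and group comparisons of circRNA parental genes against a
## sampled background of genes without detectable circRNAs.

#' Sample a background gene set
#'
#' Uniform sample without replacement, deterministic given the seed; the
#' caller's RNG state is left untouched.
#'
#' @param pool Character vector of candidate gene ids (genes without
#'   detectable circRNAs).
#' @param n Number of genes to draw.
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
sample_background <- function(pool, n, seed) {
  if (length(pool) < n) {
    stop("background pool (", length(pool), ") smaller than n (", n, ")")
  }
  with_seed(seed, sample(pool, n))
}

#' Fraction of an interval covered by repeats
#'
#' Overlapping repeat intervals are merged (union) before measuring.
#'
#' @param interval Length-2 numeric `c(start, end)` (0-based half-open) or
#'   one-row data frame with `chrom`, `start`, `end`.
#' @param repeats `data.frame` of repeat intervals (`chrom`, `start`,
#'   `end`, `class`); when `interval` is a bare vector the chrom filter is
#'   skipped.
#' @return Covered fraction in `[0, 1]`.
#' @export
repeat_fraction <- function(interval, repeats) {
  if (is.data.frame(interval)) {
    chrom <- interval$chrom[1]
    start <- interval$start[1]; end <- interval$end[1]
    repeats <- repeats[repeats$chrom == chrom, , drop = FALSE]
  } else {
    start <- interval[1]; end <- interval[2]
  }
  if (end <= start) stop("zero-length interval")
  if (!nrow(repeats)) return(0)
  rep_ir <- IRanges::reduce(to_iranges(repeats$start, repeats$end))
  ov <- IRanges::intersect(rep_ir, to_iranges(start, end))
  sum(IRanges::width(ov)) / (end - start)
}

#' Per-class breakdown of repeat bp within an interval set
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param repeats `data.frame` with `chrom`, `start`, `end`, `class`.
#' @return List with `fractions` (named vector over
#'   LTR/LINE/SINE/DNA/other, bp of each class / total repeat bp; all zero
#'   with `empty = TRUE` when no repeat bp overlaps) and `total_bp`.
#' @export
repeat_class_breakdown <- function(intervals, repeats) {
  classes <- c("LTR", "LINE", "SINE", "DNA", "other")
  iv_gr <- to_granges(intervals)
  bp <- vapply(classes, function(cl) {
    r <- repeats[repeats$class == cl, , drop = FALSE]
    if (!nrow(r)) return(0)
    r_gr <- GenomicRanges::reduce(to_granges(r))
    ov <- GenomicRanges::intersect(r_gr, GenomicRanges::reduce(iv_gr),
                                   ignore.strand = TRUE)
    sum(GenomicRanges::width(ov))
  }, 0)
  total <- sum(bp)
  list(fractions = if (total > 0) bp / total else bp * 0,
       total_bp = total, empty = total == 0)
}

#' Weighted methylation level of an interval
#'
#' Sum of methylated read counts over sum of total read counts across all
#' covered cytosines in the interval (the standard weighted methylation
#' estimator). Additive over disjoint intervals by construction.
#'
#' @param interval One-row data frame (`chrom`, `start`, `end`) or length-2
#'   numeric (then `track` must already be restricted to one chromosome).
#' @param track A `methylation_track`.
#' @param context One of `"all"` (default), `"CpG"`, `"CHG"`, `"CHH"`.
#' @return Level in `[0, 1]`; `NaN` (with attribute `no_coverage = TRUE`)
#'   when the interval contains no covered cytosine.
#' @export
weighted_methylation <- function(interval, track, context = "all") {
  if (is.data.frame(interval)) {
    track <- track[track$chrom == interval$chrom[1], , drop = FALSE]
    start <- interval$start[1]; end <- interval$end[1]
  } else {
    start <- interval[1]; end <- interval[2]
  }
  if (context != "all") {
    track <- track[track$context == context, , drop = FALSE]
  }
  inside <- track$pos >= start & track$pos < end
  total <- sum(track$total[inside])
  if (total == 0) {
    return(structure(NaN, no_coverage = TRUE))
  }
  sum(track$methylated[inside]) / total
}

#' Metagene methylation profile around a set of intervals
#'
#' Each interval body is scaled to `n_bins` bins; fixed-width flanks of
#' `flank_bp` on each side are split into `n_flank_bins` bins. Within each
#' bin the weighted methylation level is computed by pooling read counts
#' across all intervals (coverage-weighted average). Intervals are treated
#' as unstranded.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param track A `methylation_track`.
#' @param n_bins Number of body bins (default 20).
#' @param flank_bp Flank width in bp (default 2000).
#' @param n_flank_bins Number of bins per flank (default 10).
#' @return `data.frame` with `bin` (1..total), `region` (upstream / body /
#'   downstream) and `level` (NaN for bins with no covered cytosine).
#' @export
metagene_methylation_profile <- function(intervals, track, n_bins = 20,
                                         flank_bp = 2000,
                                         n_flank_bins = 10) {
  if (!nrow(intervals)) stop("empty interval set")
  total_bins <- n_flank_bins + n_bins + n_flank_bins
  meth <- numeric(total_bins)
  tot <- numeric(total_bins)
  for (i in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    tr <- track[track$chrom == chrom, , drop = FALSE]
    ## upstream flank bins
    up_edges <- seq(s - flank_bp, s, length.out = n_flank_bins + 1)
    body_edges <- seq(s, e, length.out = n_bins + 1)
    down_edges <- seq(e, e + flank_bp, length.out = n_flank_bins + 1)
    edges <- c(up_edges[-length(up_edges)], body_edges[-length(body_edges)],
               down_edges)
    bin_idx <- findInterval(tr$pos, edges, rightmost.closed = FALSE)
    ok <- bin_idx >= 1 & bin_idx <= total_bins &
      tr$pos >= edges[1] & tr$pos < edges[length(edges)]
    if (any(ok)) {
      idx <- bin_idx[ok]
      mm <- rowsum(tr$methylated[ok], idx)
      tt <- rowsum(tr$total[ok], idx)
      rows <- as.integer(rownames(mm))
      meth[rows] <- meth[rows] + mm[, 1]
      tot[rows] <- tot[rows] + tt[, 1]
    }
  }
  data.frame(
    bin = seq_len(total_bins),
    region = rep(c("upstream", "body", "downstream"),
                 c(n_flank_bins, n_bins, n_flank_bins)),
    level = ifelse(tot > 0, meth / tot, NaN),
    stringsAsFactors = FALSE
  )
}

#' Compare a feature between circular and linear groups
#'
#' Two-sided Welch t-test (pooled-variance Student available via
#' `var_equal = TRUE`), optionally on log10-transformed values, with a
#' Mann-Whitney p-value as a robustness column.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @param log10_transform Log10-transform before testing (default TRUE);
#'   non-positive values are shifted by +1 with a warning.
#' @param var_equal Use the pooled-variance Student t-test (default FALSE =
#'   Welch).
#' @return List with group sizes, means and medians (on the original
#'   scale), `t`, `p` (t-test) and `p_wilcox`.
#' @export
compare_groups <- function(values_a, values_b, log10_transform = TRUE,
                           var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  a <- values_a; b <- values_b
  if (log10_transform) {
    if (any(c(a, b) <= 0)) {
      warning("non-positive values under log10 transform; shifting by +1")
      a <- a + 1; b <- b + 1
    }
    a <- log10(a); b <- log10(b)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  pw <- tryCatch(
    suppressWarnings(stats::wilcox.test(a, b)$p.value),
    error = function(e) NA_real_
  )
  list(n_a = length(values_a), n_b = length(values_b),
       mean_a = mean(values_a), mean_b = mean(values_b),
       median_a = stats::median(values_a), median_b = stats::median(values_b),
       t = unname(tt$statistic), p = tt$p.value, p_wilcox = pw)
}
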