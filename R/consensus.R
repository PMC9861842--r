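## Consensus filtering: circRNAs called by both tools, with bounded genomic
## span and minimum junction-read support. Cross-caller read merge takes the
## per-sample maximum so the same physical reads are not double counted.

#' Consensus filter of two callers' circRNA calls
#'
#' Keeps back-splice junctions called by both tools, drops circles with a
#' genomic span above `max_length` (default 10 kb) and circles whose best
#' per-sample junction-read support is below `min_junction_reads`
#' (default 2, inclusive). Per-sample reads from the two callers are merged
#' by taking the maximum.
#'
#' @param calls_a,calls_b `circ_calls` objects with identical sample columns.
#' @param min_junction_reads Minimum of the per-sample maximum read count
#'   (inclusive).
#' @param max_length Maximum genomic span in bp (inclusive).
#' @return `data.frame` of class `circ_set`, sorted by (chrom, start, end),
#'   with columns `key`, `chrom`, `start`, `end`, `strand`, `length`,
#'   `callers` and matrix column `reads`.
#' @export
consensus_filter <- function(calls_a, calls_b, min_junction_reads = 2,
                             max_length = 10000) {
  if (min_junction_reads < 0 || max_length < 0) {
    stop("thresholds must be non-negative")
  }
  shared <- intersect(calls_a$key, calls_b$key)
  ia <- match(shared, calls_a$key)
  ib <- match(shared, calls_b$key)
  samp_a <- colnames(calls_a$reads)
  samp_b <- colnames(calls_b$reads)
  if (!identical(samp_a, samp_b)) {
    stop("caller tables have different sample columns")
  }
  reads <- pmax(calls_a$reads[ia, , drop = FALSE],
                calls_b$reads[ib, , drop = FALSE])
  out <- data.frame(key = shared,
                    chrom = calls_a$chrom[ia],
                    start = calls_a$start[ia],
                    end = calls_a$end[ia],
                    strand = calls_a$strand[ia],
                    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  keep <- out$length <= max_length &
    (if (nrow(out)) apply(reads, 1, max) else numeric(0)) >= min_junction_reads
  out <- out[keep, , drop = FALSE]
  reads <- reads[keep, , drop = FALSE]
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  reads <- reads[ord, , drop = FALSE]
  rownames(out) <- NULL
  rownames(reads) <- NULL
  out$reads <- reads
  out$callers <- rep(paste(attr(calls_a, "caller"), attr(calls_b, "caller"),
                           sep = ","), nrow(out))
  class(out) <- c("circ_set", "data.frame")
  out
}

#' Overlap statistics of two call sets
#'
#' @param calls_a,calls_b `circ_calls` objects (or anything with a `key`
#'   column).
#' @return List with `n_a`, `n_b`, `n_shared`, `n_union`, `jaccard` and
#'   `undefined` (TRUE when both sets are empty, in which case the Jaccard
#'   index is reported as 0 with a warning).
#' @export
overlap_stats <- function(calls_a, calls_b) {
  a <- unique(calls_a$key)
  b <- unique(calls_b$key)
  n_shared <- length(intersect(a, b))
  n_union <- length(union(a, b))
  undefined <- n_union == 0
  if (undefined) {
    warning("both call sets empty; Jaccard undefined, reporting 0")
  }
  list(n_a = length(a), n_b = length(b), n_shared = n_shared,
       n_union = n_union,
       jaccard = if (undefined) 0 else n_shared / n_union,
       undefined = undefined)
}
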