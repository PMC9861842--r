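## Type assignment against collapsed gene models. Decision cascade, first
## match wins:
##   1. exonic     — both junction ends fall on/within exons of one
##                   same-strand gene
##   2. intronic   — the circle lies entirely inside one intron of a
##                   same-strand gene
##   3. antisense  — the circle overlaps annotation only on the opposite
##                   strand
##   4. intergenic — no gene overlap (also the fallback for circles that
##                   touch a same-strand gene without satisfying 1 or 2)

CIRC_TYPES <- c("exonic", "intronic", "intergenic", "antisense")

## which genes overlap [start,end) on chrom
overlapping_genes <- function(models, chrom, start, end) {
  g <- models$genes
  g[g$chrom == chrom & g$start < end & g$end > start, , drop = FALSE]
}

classify_one <- function(chrom, start, end, strand, models, tol = 0) {
  res <- list(type = "intergenic", parental_gene = NA_character_,
              n_exons = NA_integer_,
              flank_left_start = NA_integer_, flank_left_end = NA_integer_,
              flank_right_start = NA_integer_, flank_right_end = NA_integer_)
  if (!chrom %in% models$genes$chrom) {
    warning("circRNA chromosome absent from annotation: ", chrom,
            " (classified intergenic)")
    return(res)
  }
  cand <- overlapping_genes(models, chrom, start, end)
  if (!nrow(cand)) {
    return(res)
  }
  same <- cand[cand$strand == strand, , drop = FALSE]

  ## rule 1: exonic
  exonic_ok <- vapply(same$gene_id, function(gid) {
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    start_in <- any(ex$start - tol <= start & start <= ex$end - 1 + tol)
    end_in <- any(ex$start + 1 - tol <= end & end <= ex$end + tol)
    start_in && end_in
  }, TRUE)
  if (any(exonic_ok)) {
    hits <- same[exonic_ok, , drop = FALSE]
    ## tie-break: gene covering the larger fraction of the circle, then id
    cov <- pmin(hits$end, end) - pmax(hits$start, start)
    hits <- hits[order(-cov, hits$gene_id), , drop = FALSE]
    gid <- hits$gene_id[1]
    ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    res$type <- "exonic"
    res$parental_gene <- gid
    res$n_exons <- count_exons(c(start, end), ex)
    intr <- gene_introns(models, gid)
    left <- intr[intr$end <= start + tol, , drop = FALSE]
    if (nrow(left)) {
      left <- left[which.max(left$end), ]
      res$flank_left_start <- left$start
      res$flank_left_end <- left$end
    }
    right <- intr[intr$start >= end - tol, , drop = FALSE]
    if (nrow(right)) {
      right <- right[which.min(right$start), ]
      res$flank_right_start <- right$start
      res$flank_right_end <- right$end
    }
    return(res)
  }

  ## rule 2: intronic
  for (gid in same$gene_id) {
    intr <- gene_introns(models, gid)
    if (nrow(intr) && any(intr$start <= start & end <= intr$end)) {
      res$type <- "intronic"
      res$parental_gene <- gid
      return(res)
    }
  }

  ## rule 3: antisense — overlap only on the opposite strand
  if (!nrow(same)) {
    anti <- cand[cand$strand != strand, , drop = FALSE]
    cov <- pmin(anti$end, end) - pmax(anti$start, start)
    anti <- anti[order(-cov, anti$gene_id), , drop = FALSE]
    res$type <- "antisense"
    res$parental_gene <- anti$gene_id[1]
    return(res)
  }

  ## same-strand overlap that is neither exonic nor intronic: fall through
  res
}

#' Classify circRNAs by type against gene models
#'
#' @param circs A `circ_set` (from [consensus_filter()]) or any data frame
#'   with `key`, `chrom`, `start`, `end`, `strand`.
#' @param models A [gene_model_set()].
#' @param boundary_tol Tolerance in bp when matching junction ends to exon
#'   boundaries (default 0 = exact).
#' @return Input with added columns `type`, `parental_gene`, `n_exons`,
#'   `flank_left_start/end`, `flank_right_start/end` (flanking introns,
#'   exonic circles only; NA where absent).
#' @export
classify_circs <- function(circs, models, boundary_tol = 0) {
  template <- list(type = character(0), parental_gene = character(0),
                   n_exons = integer(0),
                   flank_left_start = integer(0), flank_left_end = integer(0),
                   flank_right_start = integer(0),
                   flank_right_end = integer(0))
  rows <- lapply(seq_len(nrow(circs)), function(i) {
    classify_one(circs$chrom[i], circs$start[i], circs$end[i],
                 circs$strand[i], models, tol = boundary_tol)
  })
  for (col in names(template)) {
    circs[[col]] <- if (length(rows)) {
      unlist(lapply(rows, `[[`, col))
    } else {
      template[[col]]
    }
  }
  circs
}

#' Number of gene exons intersected by an exonic circRNA
#'
#' @param circ Length-2 numeric `c(start, end)` (0-based half-open) or a
#'   one-row data frame with `start`/`end`.
#' @param exons `data.frame` of the parental gene's exons.
#' @return Integer count of exons overlapping the circle.
#' @export
count_exons <- function(circ, exons) {
  if (is.data.frame(circ)) circ <- c(circ$start[1], circ$end[1])
  sum(exons$start < circ[2] & exons$end > circ[1])
}

#' Parental-gene table
#'
#' Inverse index from parental gene to the circRNAs it produces.
#'
#' @param classified Output of [classify_circs()].
#' @return `data.frame` with `gene_id`, `n_circ`, `keys` (comma-separated)
#'   and `multi` (TRUE when the gene hosts two or more circRNAs).
#' @export
parental_gene_table <- function(classified) {
  has_gene <- !is.na(classified$parental_gene) &
    classified$type %in% c("exonic", "intronic")
  d <- classified[has_gene, c("parental_gene", "key")]
  if (!nrow(d)) {
    return(data.frame(gene_id = character(), n_circ = integer(),
                      keys = character(), multi = logical(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(d$key, d$parental_gene)
  data.frame(gene_id = names(sp),
             n_circ = lengths(sp),
             keys = vapply(sp, paste, "", collapse = ","),
             multi = lengths(sp) >= 2L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Type counts and percentages
#'
#' @param classified Output of [classify_circs()].
#' @return `data.frame` with `type`, `n`, `pct` over the four circRNA types.
#' @export
type_summary <- function(classified) {
  n <- vapply(CIRC_TYPES, function(t) sum(classified$type == t), 0L)
  data.frame(type = CIRC_TYPES, n = as.integer(n),
             pct = if (sum(n) > 0) 100 * n / sum(n) else rep(0, 4),
             row.names = NULL, stringsAsFactors = FALSE)
}
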