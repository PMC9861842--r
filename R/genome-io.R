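## I/O layer. All coordinates are internal 0-based half-open; file formats
## (GFF3 1-based closed, BED 0-based half-open) are converted exactly once,
## on ingest or on write.

#' Read a genome FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  letters <- Biostrings::uniqueLetters(genome)
  if (!all(letters %in% c("A", "C", "G", "T", "N"))) {
    stop("genome alphabet outside {A,C,G,T,N}: ",
         paste(setdiff(letters, c("A", "C", "G", "T", "N")), collapse = ","))
  }
  genome
}

#' Construct a gene model set
#'
#' Container for collapsed gene models: one exon chain per gene, with
#' introns derived as the gaps between consecutive exons. All coordinates
#' 0-based half-open.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`.
#' @param exons `data.frame` with columns `gene_id`, `start`, `end`.
#' @return Object of class `gene_model_set`: list with `genes` (gene_id,
#'   chrom, strand, start, end), `exons`, and derived `introns` data frames.
#' @export
gene_model_set <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  if (any(!exons$gene_id %in% genes$gene_id)) {
    stop("exon references unknown gene_id")
  }
  if (any(exons$end <= exons$start)) {
    stop("exon with end <= start")
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  intron_list <- lapply(split(exons, exons$gene_id), function(ex) {
    ex <- ex[order(ex$start), ]
    if (any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", ex$gene_id[1])
    }
    if (nrow(ex) < 2) {
      return(NULL)
    }
    data.frame(gene_id = ex$gene_id[1],
               start = ex$end[-nrow(ex)],
               end = ex$start[-1],
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, intron_list)
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  }
  rownames(introns) <- NULL
  span <- vapply(split(exons, exons$gene_id), function(ex) {
    c(min(ex$start), max(ex$end))
  }, numeric(2))
  genes$start <- as.integer(span[1, match(genes$gene_id, colnames(span))])
  genes$end <- as.integer(span[2, match(genes$gene_id, colnames(span))])
  genes <- genes[, c("gene_id", "chrom", "strand", "start", "end")]
  rownames(genes) <- NULL
  introns$chrom <- genes$chrom[match(introns$gene_id, genes$gene_id)]
  exons$chrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$introns), "introns\n")
  invisible(x)
}

#' Introns of one gene
#'
#' @param models A `gene_model_set`.
#' @param gene_id Gene identifier.
#' @return `data.frame` of introns (0-based half-open), ordered by start.
#' @export
gene_introns <- function(models, gene_id) {
  out <- models$introns[models$introns$gene_id == gene_id, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Read gene models from GFF3
#'
#' Multi-transcript genes are collapsed to a single exon chain: the
#' transcript with the largest total exon length (ties broken by genomic
#' span, then transcript id). Exons attached directly to a gene feature are
#' treated as a single transcript. GFF3 1-based closed coordinates are
#' converted to internal 0-based half-open on ingest.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_model_set()].
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  body <- !grepl("^#", raw) & nzchar(trimws(raw))
  nfield <- lengths(strsplit(raw[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stop("malformed GFF3 line ", which(body)[nfield != 9L][1],
         ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p) {
    if (length(p)) p[[1]] else NA_character_
  }, "")

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_gene) || !any(is_exon)) {
    stop("GFF3 must contain gene and exon features")
  }
  gene_ids <- ids[is_gene]
  gene_chrom <- as.character(GenomicRanges::seqnames(gr))[is_gene]
  gene_strand <- as.character(GenomicRanges::strand(gr))[is_gene]
  gene_start0 <- GenomicRanges::start(gr)[is_gene] - 1L
  gene_end0 <- GenomicRanges::end(gr)[is_gene]

  tx_gene <- parents[is_tx]
  names(tx_gene) <- ids[is_tx]

  exon_parent <- parents[is_exon]
  exon_start0 <- GenomicRanges::start(gr)[is_exon] - 1L
  exon_end0 <- GenomicRanges::end(gr)[is_exon]
  ## exon parent may be a transcript or (bare annotations) the gene itself
  exon_tx <- exon_parent
  exon_gene <- ifelse(exon_parent %in% names(tx_gene),
                      tx_gene[exon_parent], exon_parent)
  if (any(is.na(exon_gene)) || any(!exon_gene %in% gene_ids)) {
    stop("exon with no resolvable gene parent")
  }

  exon_df <- data.frame(gene_id = exon_gene, tx_id = exon_tx,
                        start = exon_start0, end = exon_end0,
                        stringsAsFactors = FALSE)
  ## collapse to the longest transcript's exon chain
  pick <- lapply(split(exon_df, exon_df$gene_id), function(ed) {
    per_tx <- split(ed, ed$tx_id)
    total <- vapply(per_tx, function(x) sum(x$end - x$start), 0)
    span <- vapply(per_tx, function(x) max(x$end) - min(x$start), 0)
    ord <- order(-total, -span, names(per_tx))
    per_tx[[ord[1]]][, c("gene_id", "start", "end")]
  })
  exons <- do.call(rbind, pick)
  rownames(exons) <- NULL

  gi <- match(exons$gene_id, gene_ids)
  if (any(exons$start < gene_start0[gi]) || any(exons$end > gene_end0[gi])) {
    bad <- exons$gene_id[exons$start < gene_start0[gi] |
                           exons$end > gene_end0[gi]][1]
    stop("exon outside gene span for gene ", bad)
  }

  gene_model_set(
    genes = data.frame(gene_id = gene_ids, chrom = gene_chrom,
                       strand = gene_strand, stringsAsFactors = FALSE),
    exons = exons
  )
}

#' Read a caller's circRNA junction call table
#'
#' Expects a tab-separated file with header columns `chrom`, `start`, `end`,
#' `strand`, followed by one junction-read count column per sample.
#' Coordinates in the file are 0-based half-open (BED-like). Duplicate keys
#' within a caller are merged by summing their read counts.
#'
#' @param path Path to the call table.
#' @param caller_name Label for provenance, e.g. `"CIRIquant"`.
#' @return `data.frame` of class `circ_calls` with columns `key`, `chrom`,
#'   `start`, `end`, `strand` and a matrix column `reads` (one column per
#'   sample); attribute `caller`.
#' @export
read_circ_calls <- function(path, caller_name) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("call table must have columns chrom,start,end,strand + samples")
  }
  sample_cols <- setdiff(names(df), need)
  if (!length(sample_cols)) {
    stop("call table has no sample read-count columns")
  }
  reads <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(reads) <- "double"
  circ_calls(df$chrom, df$start, df$end, df$strand, reads, caller_name)
}

#' Construct a normalized caller call set
#'
#' @param chrom,start,end,strand Call coordinates (0-based half-open).
#' @param reads Numeric matrix of junction reads, one row per call, one
#'   column per sample.
#' @param caller_name Provenance label.
#' @return `circ_calls` data frame (see [read_circ_calls()]).
#' @export
circ_calls <- function(chrom, start, end, strand, reads, caller_name) {
  reads <- as.matrix(reads)
  if (any(end <= start)) {
    stop("circRNA call with end <= start")
  }
  if (any(reads < 0)) {
    stop("negative junction read count")
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be + or -")
  }
  key <- circ_key(chrom, start, end, strand)
  if (anyDuplicated(key)) {
    agg <- rowsum(reads, key)
    first <- !duplicated(key)
    ord <- match(unique(key), rownames(agg))
    reads <- agg[ord, , drop = FALSE]
    chrom <- chrom[first]; start <- start[first]; end <- end[first]
    strand <- strand[first]; key <- key[first]
  }
  out <- data.frame(key = key, chrom = chrom, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  out$reads <- reads
  attr(out, "caller") <- caller_name
  class(out) <- c("circ_calls", "data.frame")
  out
}

#' Write a caller call table
#'
#' @param calls A `circ_calls` object.
#' @param path Output path (TSV).
#' @export
write_circ_calls <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$start, end = calls$end,
                   strand = calls$strand, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(calls$reads))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-cytosine methylation track
#'
#' Five tab-separated columns: `chrom`, `pos` (0-based), `context`
#' (CpG/CHG/CHH), `methylated`, `total`.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` of class `methylation_track`.
#' @export
read_methylation <- function(path) {
  cols <- c("chrom", "pos", "context", "methylated", "total")
  if (file.size(path) == 0) {
    df <- data.frame(chrom = character(), pos = integer(),
                     context = character(), methylated = integer(),
                     total = integer(), stringsAsFactors = FALSE)
    return(methylation_track(df))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = cols)
  methylation_track(df)
}

#' Construct / validate a methylation track
#'
#' @param df `data.frame` with columns `chrom`, `pos`, `context`,
#'   `methylated`, `total`.
#' @return The validated `methylation_track`.
#' @export
methylation_track <- function(df) {
  stopifnot(all(c("chrom", "pos", "context", "methylated", "total") %in%
                  names(df)))
  if (any(df$methylated > df$total)) {
    stop("methylated read count exceeds total")
  }
  if (any(df$methylated < 0) || any(df$total < 0)) {
    stop("negative methylation counts")
  }
  if (anyDuplicated(paste(df$chrom, df$context, df$pos))) {
    stop("duplicate cytosine position within chrom+context")
  }
  class(df) <- c("methylation_track", "data.frame")
  df
}

#' Write a methylation track
#'
#' @param track A `methylation_track`.
#' @param path Output path (TSV, no header — 5 columns as in
#'   [read_methylation()]).
#' @export
write_methylation <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "pos", "context",
                                              "methylated", "total")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read repeat intervals from BED6
#'
#' The BED name field carries the repeat class (LTR, LINE, SINE, DNA,
#' other). BED 0-based half-open coordinates are kept as-is.
#'
#' @param path Path to a BED6 file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `class`.
#' @export
read_repeats <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  cls <- as.character(gr$name)
  vocab <- c("LTR", "LINE", "SINE", "DNA", "other")
  if (length(cls) && any(!cls %in% vocab)) {
    stop("repeat class outside vocabulary {LTR,LINE,SINE,DNA,other}: ",
         cls[!cls %in% vocab][1])
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             class = cls,
             stringsAsFactors = FALSE)
}

#' Write intervals to BED6
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  df <- data.frame(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name else rep(".", n),
    score = if ("score" %in% names(intervals)) intervals$score else rep(0L, n),
    strand = if ("strand" %in% names(intervals)) intervals$strand
             else rep(".", n),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED6 interval file
#'
#' @param path Path to a BED file.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `strand`
#'   (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) as.character(gr$name)
                    else rep(".", length(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write named sequences to FASTA
#'
#' @param records Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (!methods::is(records, "XStringSet")) {
    records <- Biostrings::DNAStringSet(records)
  }
  Biostrings::writeXStringSet(records, path)
}

#' Extract the spliced mRNA sequence of a gene
#'
#' Concatenates the exon sequences of the collapsed model in genomic order
#' and reverse-complements for minus-strand genes.
#'
#' @param genome A genome `DNAStringSet`.
#' @param models A `gene_model_set`.
#' @param gene_id Gene identifier.
#' @return Character scalar DNA sequence.
#' @export
spliced_sequence <- function(genome, models, gene_id) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(g) != 1) stop("unknown gene_id: ", gene_id)
  if (!g$chrom %in% names(genome)) stop("chromosome missing: ", g$chrom)
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  parts <- vapply(seq_len(nrow(ex)), function(i) {
    as.character(Biostrings::subseq(genome[[g$chrom]],
                                    ex$start[i] + 1L, ex$end[i]))
  }, "")
  s <- paste(parts, collapse = "")
  if (g$strand == "-") s <- revcomp(s)
  s
}

#' Read a count matrix (features x samples) from TSV
#'
#' First column `id`, remaining columns one per sample.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Write a count matrix to TSV
#'
#' @param mat Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read per-sample library sizes from a two-column TSV
#'
#' @param path TSV with columns `sample`, `clean_reads`.
#' @return Named numeric vector.
#' @export
read_lib_sizes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}
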