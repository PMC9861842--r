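#' Build a circRNA identifier key
#'
#' Keys have the form `"chrom:start|end:strand"` with 0-based half-open
#' coordinates, so the same back-splice junction called by different tools
#' collapses to the same string.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval of the circle.
#' @param strand `"+"` or `"-"`.
#' @return Character vector of keys.
#' @export
circ_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d|%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse circRNA keys back into coordinates
#'
#' @param key Character vector of keys as built by [circ_key()].
#' @return `data.frame` with columns `key`, `chrom`, `start`, `end`, `strand`.
#' @export
parse_circ_key <- function(key) {
  m <- regmatches(key, regexec("^(.+):([0-9]+)\\|([0-9]+):([+-])$", key))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("malformed circRNA key: ", key[bad][1])
  }
  data.frame(
    key = key,
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    strand = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. Keeps package determinism independent of
## the session RNG.
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required (no silent nondeterminism)")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## 0-based half-open intervals -> IRanges (1-based closed)
to_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

## interval df (chrom,start,end) -> GRanges
to_granges <- function(df, strand = NULL) {
  s <- if (is.null(strand)) "*" else strand
  GenomicRanges::GRanges(df$chrom, to_iranges(df$start, df$end), strand = s)
}
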