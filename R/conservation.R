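## Conservation scoring by two routes: (1) junction-anchored local
## alignment of back-splice junction sequences, requiring the aligned
## region to cover the junction; (2) alignment-free k-mer profile
## correlation (length-normalized, background-standardized counts of all
## 4^k k-mers, compared by Pearson correlation with a conserved call at
## r > 0.2, strict).

#' Build the back-splice junction sequence of a circRNA
#'
#' The junction sequence joins the last `min(100, L)` bases of the circle
#' to its first `min(100, L)` bases (L = genomic span), i.e. the sequence a
#' read spanning the back-splice junction would traverse. Minus-strand
#' circles are reverse-complemented before the rule is applied, so the
#' junction is always in transcript orientation.
#'
#' @param circ One-row data frame (or list) with `key`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @param genome Genome `DNAStringSet`.
#' @param flank Maximum bases taken from each side of the junction
#'   (default 100).
#' @return List with `key`, `seq` (character), `junction_offset` (length of
#'   the first segment; the junction lies between positions
#'   `junction_offset` and `junction_offset + 1`, 1-based).
#' @export
build_junction_sequence <- function(circ, genome, flank = 100) {
  chrom <- circ$chrom[1]
  if (!chrom %in% names(genome)) {
    stop("circRNA on missing chromosome: ", chrom)
  }
  start <- circ$start[1]; end <- circ$end[1]
  L <- end - start
  if (start < 0 || end > length(genome[[chrom]])) {
    stop("circRNA coordinates outside chromosome: ", circ$key[1])
  }
  m <- min(flank, L)
  circ_seq <- as.character(Biostrings::subseq(genome[[chrom]],
                                              start + 1L, end))
  if (circ$strand[1] == "-") circ_seq <- revcomp(circ_seq)
  seq <- paste0(substr(circ_seq, L - m + 1L, L), substr(circ_seq, 1L, m))
  list(key = circ$key[1], seq = seq, junction_offset = m)
}

#' Junction sequences for a set of circRNAs
#'
#' @param circs `circ_set`-like data frame.
#' @param genome Genome `DNAStringSet`.
#' @param flank See [build_junction_sequence()].
#' @return List with `seqs` (named character vector, names = keys) and
#'   `offsets` (named integer vector of junction offsets).
#' @export
build_junction_sequences <- function(circs, genome, flank = 100) {
  js <- lapply(seq_len(nrow(circs)), function(i) {
    build_junction_sequence(circs[i, , drop = FALSE], genome, flank)
  })
  list(seqs = stats::setNames(vapply(js, `[[`, "", "seq"),
                              vapply(js, `[[`, "", "key")),
       offsets = stats::setNames(vapply(js, function(x)
         as.integer(x$junction_offset), 1L),
         vapply(js, `[[`, "", "key")))
}

#' Raw k-mer profiles, length-normalized
#'
#' Counts of all 4^k k-mers per sequence, divided by sequence length in kb
#' (counts per kb).
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param k k-mer length (default 6).
#' @return Numeric matrix, rows = sequences, columns = the 4^k k-mers.
#' @export
kmer_counts <- function(seqs, k = 6) {
  ss <- if (methods::is(seqs, "DNAStringSet")) seqs
        else Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(ss, width = k)
  rownames(counts) <- names(ss)
  counts / (Biostrings::width(ss) / 1000)
}

#' Standardize k-mer profiles against a background set
#'
#' Each k-mer component is z-scored using the mean and standard deviation
#' of that component across the background profiles (by default the
#' profiles themselves, i.e. the union of sequences in the comparison).
#' Components with zero background variance are set to 0.
#'
#' @param counts Matrix from [kmer_counts()].
#' @param background Matrix of background profiles (same columns).
#' @return Standardized matrix of the same shape as `counts`.
#' @export
standardize_profiles <- function(counts, background = counts) {
  mu <- colMeans(background)
  sd <- apply(background, 2, stats::sd)
  z <- sweep(counts, 2, mu, "-")
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), "/")
  z[, sd == 0] <- 0
  z
}

#' Pearson correlation of two standardized k-mer profiles
#'
#' @param profile_a,profile_b Numeric vectors (rows of a standardized
#'   profile matrix).
#' @param r_cutoff Conservation cutoff (default 0.2); the conserved call
#'   is strict (`r > r_cutoff`), so a correlation exactly at the cutoff is
#'   not conserved.
#' @return List with `r` (NaN when either profile has zero variance, with
#'   `undefined = TRUE`) and `conserved` (`r > r_cutoff`, strict).
#' @export
kmer_pearson <- function(profile_a, profile_b, r_cutoff = 0.2) {
  if (stats::sd(profile_a) == 0 || stats::sd(profile_b) == 0) {
    return(list(r = NaN, conserved = FALSE, undefined = TRUE))
  }
  r <- stats::cor(profile_a, profile_b)
  list(r = r, conserved = is.finite(r) && r > r_cutoff, undefined = FALSE)
}

## ---- local alignment -------------------------------------------------

## Affine-gap Smith-Waterman. A gap of length g costs open + g * extend.
## Returns the best local score and the 1-based query/subject spans of the
## best alignment. O(mn); fine at junction-sequence scale (<= 200 bp).
sw_local <- function(query, subject, match = 1, mismatch = -2,
                     gap_open = 5, gap_extend = 2) {
  q <- utf8ToInt(query); s <- utf8ToInt(subject)
  m <- length(q); n <- length(s)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)        # ends in a match/mismatch
  Ix <- matrix(NEG, m + 1, n + 1)     # ends in a gap in subject (query base)
  Iy <- matrix(NEG, m + 1, n + 1)     # ends in a gap in query (subject base)
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(m)) {
    sub_score <- ifelse(q[i] == s, match, mismatch)
    for (j in seq_len(n)) {
      diag_best <- max(M[i, j], Ix[i, j], Iy[i, j], 0)
      M[i + 1, j + 1] <- diag_best + sub_score[j]
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; bi <- i; bj <- j
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, q_start = NA_integer_, q_end = NA_integer_,
                s_start = NA_integer_, s_end = NA_integer_,
                n_match = 0L, align_len = 0L))
  }
  ## traceback from the best cell, which always ends in state M
  i <- bi; j <- bj; state <- "M"
  n_match <- 0L; align_len <- 0L
  qs <- bi; ss <- bj
  repeat {
    if (state == "M") {
      align_len <- align_len + 1L
      if (q[i] == s[j]) n_match <- n_match + 1L
      qs <- i; ss <- j
      prev <- c(M = M[i, j], Ix = Ix[i, j], Iy = Iy[i, j])
      if (max(prev) <= 0) break   # local alignment starts here
      state <- names(prev)[which.max(prev)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {   # query base i against a gap
      align_len <- align_len + 1L
      qs <- i
      from_open <- M[i, j + 1] - gap_open - gap_extend
      from_ext <- Ix[i, j + 1] - gap_extend
      state <- if (from_open >= from_ext) "M" else "Ix"
      i <- i - 1L
    } else {                      # Iy: subject base j against a gap
      align_len <- align_len + 1L
      ss <- j
      from_open <- M[i + 1, j] - gap_open - gap_extend
      from_ext <- Iy[i + 1, j] - gap_extend
      state <- if (from_open >= from_ext) "M" else "Iy"
      j <- j - 1L
    }
    if (i < 1 || j < 1) break
  }
  list(score = best, q_start = qs, q_end = bi, s_start = ss, s_end = bj,
       n_match = n_match, align_len = align_len)
}

## Karlin-Altschul E-value for an ungapped-style score under the +1/-2
## scheme. Constants stated so results are bit-for-bit reproducible.
karlin_evalue <- function(score, m, n, K = 0.711, lambda = 1.37) {
  K * m * n * exp(-lambda * score)
}

## do query and subject share any exact word of length w?
has_seed <- function(query, subject, word = 11) {
  if (nchar(query) < word) {
    stop("query shorter than seed word (", word, ")")
  }
  if (nchar(subject) < word) return(FALSE)
  qw <- substring(query, seq_len(nchar(query) - word + 1),
                  seq_len(nchar(query) - word + 1) + word - 1)
  sw <- substring(subject, seq_len(nchar(subject) - word + 1),
                  seq_len(nchar(subject) - word + 1) + word - 1)
  any(qw %in% sw)
}

#' Junction-anchored conservation search
#'
#' Word-seeded gapped local alignment of one junction sequence against a
#' subject database. A hit is reported when the Karlin-Altschul E-value is
#' at or below `evalue_max` and the alignment's query span strictly
#' contains the two junction-adjacent bases (the alignment must extend
#' beyond them on both sides), i.e. the junction site is covered by the
#' aligned region.
#'
#' @param query List from [build_junction_sequence()] (fields `key`, `seq`,
#'   `junction_offset`).
#' @param subject_db Named character vector of subject sequences.
#' @param species Named character vector mapping subject names to species
#'   labels (optional).
#' @param word Seed word length (default 11).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (+1/-2/5/2).
#' @return `data.frame` with one row per subject hit: `query`, `subject`,
#'   `species`, `score`, `evalue`, `identity`, `junction_covered`.
#' @export
junction_conserved <- function(query, subject_db, species = NULL, word = 11,
                               evalue_max = 1e-5, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2) {
  jo <- query$junction_offset
  hits <- lapply(names(subject_db), function(sname) {
    subj <- subject_db[[sname]]
    if (!has_seed(query$seq, subj, word)) return(NULL)
    al <- sw_local(query$seq, subj, match, mismatch, gap_open, gap_extend)
    ev <- karlin_evalue(al$score, nchar(query$seq), nchar(subj))
    if (ev > evalue_max) return(NULL)
    covered <- !is.na(al$q_start) && al$q_start < jo && al$q_end > jo + 1
    data.frame(query = query$key, subject = sname,
               species = if (!is.null(species)) species[[sname]]
                         else NA_character_,
               score = al$score, evalue = ev,
               identity = if (al$align_len > 0)
                 100 * al$n_match / al$align_len else NA_real_,
               junction_covered = covered, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(query = character(), subject = character(),
                      species = character(), score = numeric(),
                      evalue = numeric(), identity = numeric(),
                      junction_covered = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' k-mer conservation screen of a query set against a subject set
#'
#' Profiles are standardized against the union of query and subject
#' sequences, then every query/subject pair is scored by Pearson
#' correlation; a query is conserved when any subject exceeds r > 0.2.
#'
#' @param query_seqs,subject_seqs Named character vectors.
#' @param k k-mer length (default 6).
#' @param r_cutoff Conservation cutoff on Pearson r (strictly greater;
#'   default 0.2).
#' @return `data.frame` with `query`, `subject`, `r`, `conserved`.
#' @export
kmer_conservation <- function(query_seqs, subject_seqs, k = 6,
                              r_cutoff = 0.2) {
  all_counts <- kmer_counts(c(query_seqs, subject_seqs), k)
  z <- standardize_profiles(all_counts)
  qz <- z[seq_along(query_seqs), , drop = FALSE]
  sz <- z[length(query_seqs) + seq_along(subject_seqs), , drop = FALSE]
  grid <- expand.grid(q = seq_along(query_seqs), s = seq_along(subject_seqs))
  r <- vapply(seq_len(nrow(grid)), function(i) {
    a <- qz[grid$q[i], ]; b <- sz[grid$s[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NaN else stats::cor(a, b)
  }, 0)
  data.frame(query = names(query_seqs)[grid$q],
             subject = names(subject_seqs)[grid$s],
             r = r,
             conserved = !is.nan(r) & r > r_cutoff,
             stringsAsFactors = FALSE)
}

#' Summarize conserved fractions
#'
#' @param hits `data.frame` of hits with columns `query`, `species`, and a
#'   logical column telling whether each hit counts as conserved
#'   (`junction_covered` for alignment hits, `conserved` for k-mer hits).
#' @param n_query Total number of query circRNAs screened.
#' @param conserved_col Name of the logical column (default auto-detected).
#' @param exclude_species Species label(s) to exclude (e.g. the query's own
#'   species) for the cross-species fraction.
#' @return List with `n_conserved`, `fraction` (percent of queries), per
#'   species counts, and `fraction_cross_species` when `exclude_species`
#'   is given.
#' @export
conservation_summary <- function(hits, n_query, conserved_col = NULL,
                                 exclude_species = NULL) {
  if (n_query <= 0) stop("n_query must be positive")
  if (is.null(conserved_col)) {
    conserved_col <- intersect(c("junction_covered", "conserved"),
                               names(hits))[1]
  }
  ok <- hits[hits[[conserved_col]] %in% TRUE, , drop = FALSE]
  n_cons <- length(unique(ok$query))
  per_species <- if (nrow(ok) && "species" %in% names(ok)) {
    tapply(ok$query, ok$species, function(q) length(unique(q)))
  } else {
    integer(0)
  }
  out <- list(n_query = n_query, n_conserved = n_cons,
              fraction = 100 * n_cons / n_query,
              per_species = per_species)
  if (!is.null(exclude_species)) {
    keep <- ok[!ok$species %in% exclude_species, , drop = FALSE]
    out$n_conserved_cross_species <- length(unique(keep$query))
    out$fraction_cross_species <- 100 * out$n_conserved_cross_species /
      n_query
  }
  out
}
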