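## miRNA target-site prediction with an expectation score, and assembly of
## the DE-constrained circRNA-miRNA-mRNA sponge network. The scoring
## scheme follows the published defaults of plant small-RNA target
## predictors: per aligned position (numbered from the miRNA 5' end)
## match 0, G:U wobble 0.5, mismatch 1.0, gap 2.0, with penalties doubled
## in the seed-critical region (positions 2-13); a site is reported when
## the summed expectation is at or below the cutoff (default 5.0).

VALID_DNA <- c("A", "C", "G", "T")

## penalty states for reverse-complemented miRNA chars vs target chars:
## match when equal; G:U wobble when the miRNA G pairs a target T
## (rc char C vs target T) or the miRNA U pairs a target G (rc char A vs
## target G); mismatch otherwise.
pair_state <- function(rc_char, t_char) {
  ifelse(rc_char == t_char, "match",
         ifelse((rc_char == "C" & t_char == "T") |
                  (rc_char == "A" & t_char == "G"), "gu", "mismatch"))
}

state_penalty <- function(state, w_gu, w_mm) {
  ifelse(state == "match", 0, ifelse(state == "gu", w_gu, w_mm))
}

## alignment shapes: ungapped; one target gap (a miRNA position aligned to
## nothing, window m-1); one miRNA gap (an unpaired target base, window
## m+1). Returns, per window start, the best (lowest-expectation) shape.
#' Predict miRNA binding sites on a target sequence
#'
#' Slides the reverse complement of the miRNA along the target, allowing
#' at most one gap, and scores each candidate site by the expectation
#' penalty scheme described above. Sites must additionally have at most
#' `max_mismatch` mismatches and no run of more than 2 consecutive
#' mismatches within the seed-critical region.
#'
#' @param mirna Mature miRNA sequence, 5'->3', RNA or DNA alphabet
#'   (18-24 nt).
#' @param target_sequence Target DNA sequence (length >= miRNA length).
#' @param max_expectation Expectation cutoff, inclusive (default 5.0).
#' @param seed_region miRNA positions with doubled penalties (default
#'   2:13).
#' @param w_gu,w_mismatch,w_gap Penalty weights (0.5 / 1.0 / 2.0).
#' @param max_mismatch Maximum mismatches per site (default 4).
#' @return `data.frame` with `target_start` (0-based position on the
#'   target), `target_len` (bases of target covered), `expectation`,
#'   `n_mismatch`, `n_gu`, `n_gap`.
#' @export
predict_sites <- function(mirna, target_sequence, max_expectation = 5.0,
                          seed_region = 2:13, w_gu = 0.5, w_mismatch = 1.0,
                          w_gap = 2.0, max_mismatch = 4) {
  mirna <- toupper(chartr("Uu", "Tt", mirna))
  target_sequence <- toupper(target_sequence)
  mchars <- strsplit(mirna, "")[[1]]
  tchars <- strsplit(target_sequence, "")[[1]]
  if (any(!mchars %in% VALID_DNA)) stop("invalid miRNA alphabet")
  if (any(!tchars %in% c(VALID_DNA, "N"))) stop("invalid target alphabet")
  m <- length(mchars)
  if (m < 18 || m > 24) stop("miRNA length must be 18-24 nt")
  Lt <- length(tchars)
  if (Lt < m) stop("target shorter than miRNA")

  rc <- strsplit(revcomp(mirna), "")[[1]]
  ## miRNA position of alignment column j (rc index j): 5'-end position m
  ## maps to rc index 1
  mir_pos <- m:1
  mult <- ifelse(mir_pos %in% seed_region, 2, 1)

  score_shape <- function(col_target_offset, gap_col = NULL,
                          extra_base = FALSE) {
    ## col_target_offset: for each rc column, offset of the target base
    ## relative to the window start (NA = gap in target)
    win_len <- if (extra_base) m + 1L else if (!is.null(gap_col)) m - 1L
               else m
    n_win <- Lt - win_len + 1L
    if (n_win < 1) return(NULL)
    pen <- matrix(0, nrow = m, ncol = n_win)
    mism <- matrix(FALSE, nrow = m, ncol = n_win)
    gu <- matrix(FALSE, nrow = m, ncol = n_win)
    for (j in seq_len(m)) {
      if (is.na(col_target_offset[j])) {
        pen[j, ] <- w_gap * mult[j]
        next
      }
      tb <- tchars[seq_len(n_win) + col_target_offset[j]]
      st <- pair_state(rc[j], tb)
      pen[j, ] <- state_penalty(st, w_gu, w_mismatch) * mult[j]
      mism[j, ] <- st == "mismatch"
      gu[j, ] <- st == "gu"
    }
    gap_pen <- if (extra_base) w_gap * mult[gap_col] else 0
    exp_tot <- colSums(pen) + gap_pen
    n_mm <- colSums(mism)
    ## only candidate windows need the remaining (more expensive) filters
    cand <- which(exp_tot <= max_expectation & n_mm <= max_mismatch)
    if (!length(cand)) return(NULL)
    ## longest run of consecutive mismatches within the seed region,
    ## evaluated in miRNA position order
    seed_cols <- which(mir_pos %in% seed_region)
    seed_cols <- seed_cols[order(mir_pos[seed_cols])]
    run <- apply(mism[seed_cols, cand, drop = FALSE], 2, function(v) {
      r <- rle(v)
      if (any(r$values)) max(r$lengths[r$values]) else 0L
    })
    data.frame(target_start = cand - 1L,
               target_len = win_len,
               expectation = exp_tot[cand],
               n_mismatch = n_mm[cand],
               n_gu = colSums(gu[, cand, drop = FALSE]),
               n_gap = if (!is.null(gap_col) || any(is.na(col_target_offset)))
                 1L else 0L,
               seed_mismatch_run = run,
               stringsAsFactors = FALSE)
  }

  shapes <- list(score_shape(0:(m - 1)))
  ## one gap in the target: rc column g unaligned
  for (g in seq_len(m)) {
    off <- rep(NA_integer_, m)
    off[seq_len(m) < g] <- seq_len(sum(seq_len(m) < g)) - 1L
    if (g < m) off[(g + 1):m] <- seq(g, m - 1) - 1L
    shapes[[length(shapes) + 1]] <- score_shape(off)
  }
  ## one gap in the miRNA: an extra target base between columns g-1 and g
  for (g in 2:m) {
    off <- integer(m)
    off[seq_len(g - 1)] <- seq_len(g - 1) - 1L
    off[g:m] <- g:m
    shapes[[length(shapes) + 1]] <- score_shape(off, gap_col = g,
                                                extra_base = TRUE)
  }
  shapes <- shapes[!vapply(shapes, is.null, TRUE)]
  empty <- data.frame(target_start = integer(), target_len = integer(),
                      expectation = numeric(), n_mismatch = integer(),
                      n_gu = integer(), n_gap = integer(),
                      stringsAsFactors = FALSE)
  if (!length(shapes)) return(empty)
  all_sites <- do.call(rbind, shapes)
  sites <- all_sites[all_sites$seed_mismatch_run <= 2, , drop = FALSE]
  if (!nrow(sites)) return(empty)
  ## best shape per window start
  sites <- sites[order(sites$target_start, sites$expectation), , drop = FALSE]
  sites <- sites[!duplicated(sites$target_start), , drop = FALSE]
  rownames(sites) <- NULL
  sites[, c("target_start", "target_len", "expectation", "n_mismatch",
            "n_gu", "n_gap")]
}

#' Predict miRNA sites on a circRNA junction sequence
#'
#' Runs [predict_sites()] for each miRNA against the circular junction
#' sequence, so sites spanning the back-splice junction are detectable.
#'
#' @param junction List from [build_junction_sequence()].
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param ... Passed to [predict_sites()].
#' @return `data.frame` with `target` (circ key), `mirna`, site columns,
#'   and `junction_spanning` (TRUE when the site crosses the back-splice
#'   junction).
#' @export
circ_sites_on_junction <- function(junction, mirnas, ...) {
  jo <- junction$junction_offset
  rows <- lapply(names(mirnas), function(mid) {
    s <- predict_sites(mirnas[[mid]], junction$seq, ...)
    if (!nrow(s)) return(NULL)
    s$target <- junction$key
    s$mirna <- mid
    s$junction_spanning <- s$target_start < jo &
      s$target_start + s$target_len > jo
    s
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target_start = integer(), target_len = integer(),
                      expectation = numeric(), n_mismatch = integer(),
                      n_gu = integer(), n_gap = integer(),
                      target = character(), mirna = character(),
                      junction_spanning = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Predict miRNA sites on a set of mRNA sequences
#'
#' @param mrna_seqs Named character vector of spliced transcript sequences.
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param ... Passed to [predict_sites()].
#' @return `data.frame` with `target` (gene id), `mirna` and site columns.
#' @export
mrna_sites <- function(mrna_seqs, mirnas, ...) {
  rows <- lapply(names(mrna_seqs), function(gid) {
    per_mir <- lapply(names(mirnas), function(mid) {
      s <- predict_sites(mirnas[[mid]], mrna_seqs[[gid]], ...)
      if (!nrow(s)) return(NULL)
      s$target <- gid
      s$mirna <- mid
      s
    })
    do.call(rbind, per_mir)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target_start = integer(), target_len = integer(),
                      expectation = numeric(), n_mismatch = integer(),
                      n_gu = integer(), n_gap = integer(),
                      target = character(), mirna = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Assemble the circRNA-miRNA-mRNA sponge network
#'
#' Keeps circ-miRNA edges whose circRNA is differentially expressed and
#' miRNA-mRNA edges whose mRNA is differentially expressed, then prunes
#' miRNAs lacking either edge type. The result is tripartite by
#' construction: no circ-mRNA edges exist.
#'
#' @param de_circ_keys Keys of differentially expressed circRNAs.
#' @param de_gene_ids Ids of differentially expressed genes.
#' @param circ_sites `data.frame` of circRNA binding sites (`target`,
#'   `mirna`, `expectation`).
#' @param gene_sites `data.frame` of mRNA binding sites (same columns).
#' @return Object of class `sponge_network`: list with `nodes`
#'   (`data.frame` id/type), `edges` (`data.frame` source/target/
#'   edge_type/expectation) and `counts` (n_circ, n_mirna, n_mrna,
#'   n_edges).
#' @export
build_network <- function(de_circ_keys, de_gene_ids, circ_sites,
                          gene_sites) {
  ce <- unique(circ_sites[circ_sites$target %in% de_circ_keys,
                          c("target", "mirna", "expectation")])
  ge <- unique(gene_sites[gene_sites$target %in% de_gene_ids,
                          c("target", "mirna", "expectation")])
  ## collapse multiple sites on the same pair to the best expectation
  collapse <- function(d) {
    if (!nrow(d)) return(d)
    d <- d[order(d$target, d$mirna, d$expectation), , drop = FALSE]
    d[!duplicated(d[, c("target", "mirna")]), , drop = FALSE]
  }
  ce <- collapse(ce); ge <- collapse(ge)
  keep_mir <- intersect(unique(ce$mirna), unique(ge$mirna))
  ce <- ce[ce$mirna %in% keep_mir, , drop = FALSE]
  ge <- ge[ge$mirna %in% keep_mir, , drop = FALSE]
  edges <- rbind(
    data.frame(source = ce$target, target = ce$mirna,
               edge_type = rep("circ-miRNA", nrow(ce)),
               expectation = ce$expectation, stringsAsFactors = FALSE),
    data.frame(source = ge$mirna, target = ge$target,
               edge_type = rep("miRNA-mRNA", nrow(ge)),
               expectation = ge$expectation, stringsAsFactors = FALSE)
  )
  circ_ids <- unique(ce$target)
  mrna_ids <- unique(ge$target)
  nodes <- data.frame(
    id = c(circ_ids, keep_mir, mrna_ids),
    type = rep(c("circ", "miRNA", "mRNA"),
               c(length(circ_ids), length(keep_mir), length(mrna_ids))),
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL; rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 counts = c(n_circ = sum(nodes$type == "circ"),
                            n_mirna = sum(nodes$type == "miRNA"),
                            n_mrna = sum(nodes$type == "mRNA"),
                            n_edges = nrow(edges))),
            class = "sponge_network")
}

#' @export
print.sponge_network <- function(x, ...) {
  cat("sponge_network:", x$counts["n_circ"], "circRNAs,",
      x$counts["n_mirna"], "miRNAs,", x$counts["n_mrna"], "mRNAs,",
      x$counts["n_edges"], "edges\n")
  invisible(x)
}

#' Export a sponge network as edge-list and node-attribute tables
#'
#' @param network A `sponge_network`.
#' @param edges_path Output TSV for edges (source, target, edge_type,
#'   expectation).
#' @param nodes_path Output TSV for node attributes (id, type).
#' @export
export_network <- function(network, edges_path, nodes_path) {
  utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(network)
}
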