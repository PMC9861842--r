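## Seeded synthetic fixture generator. Emits a complete input bundle —
## genome FASTA, GFF3 annotation, repeat BED, per-cytosine methylation
## track, two caller call tables, count matrices, miRNA FASTA and a
## conservation subject set — with a truth table of everything planted, so
## every downstream stage can be validated against known ground truth.
## The study design mirrored is 5 chilling timepoints (CK, C6, C12, C24,
## C7d) with 3 biological replicates.

SIM_TIMEPOINTS <- c("CK", "C6", "C12", "C24", "C7d")

#' Simulation configuration
#'
#' Defaults emulate a compact plant genome slice with overdispersed
#' junction-read counts (negative binomial, dispersion 0.1), repeat- and
#' methylation-enriched flanking introns around planted circRNAs, and a
#' planted sponge layer of circRNA-miRNA-mRNA triples.
#'
#' @param seed Integer seed (mandatory; the generator refuses to run
#'   without one).
#' @param n_chromosomes,chrom_length Genome shape (default 2 x 200 kb).
#' @param n_genes Number of genes placed (default 50).
#' @param exons_per_gene Integer range (default 3-7).
#' @param exon_length,intron_length,intergenic_gap bp ranges for uniform
#'   sampling.
#' @param n_circ Named integer vector of planted circRNAs per type;
#'   default `c(exonic = 28, intronic = 8, intergenic = 3, antisense = 1)`,
#'   the dominance ordering typical of plant circRNA surveys.
#' @param caller_overlap_fraction Fraction of planted circRNAs present in
#'   both caller tables (default 1).
#' @param n_decoys_per_caller Caller-specific false calls per tool
#'   (default 12).
#' @param mean_junction_reads,dispersion Negative-binomial junction-read
#'   model (default mean 60, dispersion 0.1).
#' @param n_replicates Biological replicates per timepoint (default 3).
#' @param timepoints Timepoint labels; the first is the untreated
#'   reference.
#' @param n_de_circ,de_circ_fold Planted differentially expressed
#'   circRNAs and their fold (default 8 at 4-fold; roughly the top
#'   five-eighths up, the rest down).
#' @param n_de_genes,de_gene_fold Planted DE genes (default 12 at 4-fold).
#' @param gene_mean_reads Baseline mean fragment count for genes
#'   (default 200).
#' @param repeat_background,repeat_enrichment Target repeat coverage of
#'   background vs circ-flanking introns (default 0.08 vs 0.35).
#' @param meth_background,meth_elevation Mean weighted methylation of
#'   background regions vs circ-flanking introns (default 0.25 vs 0.65).
#' @param meth_coverage Mean per-cytosine read coverage (Poisson;
#'   default 20).
#' @param n_mirnas,mirna_length Mature miRNA pool (default 8 x 21 nt).
#' @param n_sponge Planted sponge triples (circ, miRNA, mRNA; default 5).
#' @param n_conserved_subjects Planted conserved subject sequences
#'   (mutated copies of planted junction sequences; default 6).
#' @param subject_mutation_rate Substitution rate applied to conserved
#'   subjects (default 0.05).
#' @param n_random_subjects Unrelated subject sequences (default 15).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_chromosomes = 2,
                       chrom_length = 220000,
                       n_genes = 50,
                       exons_per_gene = c(3, 7),
                       exon_length = c(120, 400),
                       intron_length = c(300, 1500),
                       intergenic_gap = c(600, 3000),
                       n_circ = c(exonic = 28, intronic = 8,
                                  intergenic = 3, antisense = 1),
                       caller_overlap_fraction = 1,
                       n_decoys_per_caller = 12,
                       mean_junction_reads = 60,
                       dispersion = 0.1,
                       n_replicates = 3,
                       timepoints = SIM_TIMEPOINTS,
                       n_de_circ = 8,
                       de_circ_fold = 4,
                       n_de_genes = 12,
                       de_gene_fold = 4,
                       gene_mean_reads = 200,
                       repeat_background = 0.08,
                       repeat_enrichment = 0.35,
                       meth_background = 0.25,
                       meth_elevation = 0.65,
                       meth_coverage = 20,
                       n_mirnas = 8,
                       mirna_length = 21,
                       n_sponge = 5,
                       n_conserved_subjects = 6,
                       subject_mutation_rate = 0.05,
                       n_random_subjects = 15) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("sim_config requires a seed (no silent nondeterminism)")
  }
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("n_chromosomes", "chrom_length", "n_genes",
                             "mean_junction_reads", "n_replicates",
                             "gene_mean_reads", "meth_coverage",
                             "n_mirnas", "mirna_length")]) > 0),
            n_decoys_per_caller >= 0)
  if (caller_overlap_fraction < 0 || caller_overlap_fraction > 1) {
    stop("caller_overlap_fraction must be in [0,1]")
  }
  if (de_circ_fold <= 0 || de_gene_fold <= 0) {
    stop("planted fold changes must be positive")
  }
  if (!all(names(n_circ) %in% CIRC_TYPES) || any(n_circ < 0)) {
    stop("n_circ must be a named vector over the four circRNA types")
  }
  if (n_sponge > n_de_circ) stop("n_sponge cannot exceed n_de_circ")
  if (n_de_circ > sum(n_circ)) stop("n_de_circ exceeds planted circRNAs")
  class(cfg) <- "sim_config"
  cfg
}

## uniform integer in [a, b]
runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## place non-overlapping genes along the chromosomes; returns genes/exons
## data frames in 0-based half-open coordinates
place_genes <- function(cfg, plus_strand_first = 0) {
  genes <- list(); exons <- list()
  gid <- 0
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    pos <- runif_int(1, cfg$intergenic_gap)
    repeat {
      if (gid >= cfg$n_genes) break
      k <- runif_int(1, cfg$exons_per_gene)
      ex_len <- runif_int(k, cfg$exon_length)
      in_len <- runif_int(k - 1, cfg$intron_length)
      g_len <- sum(ex_len) + sum(in_len)
      if (pos + g_len > cfg$chrom_length - 200) break
      gid <- gid + 1
      id <- sprintf("G%04d", gid)
      starts <- pos + cumsum(c(0, ex_len[-k] + in_len))
      strand <- if (gid <= plus_strand_first) "+"
                else sample(c("+", "-"), 1)
      genes[[gid]] <- data.frame(gene_id = id, chrom = chrom,
                                 strand = strand, stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(gene_id = id, start = starts,
                                 end = starts + ex_len,
                                 stringsAsFactors = FALSE)
      pos <- pos + g_len + runif_int(1, cfg$intergenic_gap)
    }
  }
  if (gid < cfg$n_genes) {
    stop("genome too small to place ", cfg$n_genes, " genes; increase ",
         "chrom_length or n_chromosomes")
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

## internal GFF3 writer for the generator (1-based closed on disk)
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    ex <- models$exons[models$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), ]
    tx <- paste0(g$gene_id, ".t1")
    lines <- c(
      lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start + 1L, g$end, g$strand, tx, g$gene_id),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              ex$chrom, ex$start + 1L, ex$end, g$strand, tx,
              seq_len(nrow(ex)), tx)
    )
  }
  writeLines(lines, path)
}

## draw a junction-read count matrix: one row per feature, samples are
## timepoint x replicate; `folds` multiply the baseline mean at every
## non-reference timepoint
draw_count_matrix <- function(base_means, folds, timepoints, n_reps,
                              dispersion, ids) {
  samples <- paste0(rep(timepoints, each = n_reps), "_R",
                    seq_len(n_reps))
  is_ref <- rep(timepoints == timepoints[1], each = n_reps)
  mat <- matrix(0L, nrow = length(base_means), ncol = length(samples),
                dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    mu <- if (is_ref[j]) base_means else base_means * folds
    mat[, j] <- stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  mat
}

#' Generate the synthetic fixture bundle
#'
#' Deterministic given `config$seed`: running twice with the same seed
#' produces byte-identical files. See [sim_config()] for what is planted.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Object of class `sim_bundle`: list with `paths` (named file
#'   paths), `truth` (circ table, sponge triples, DE genes, conserved
#'   keys), `samples`, `models` and the `config`.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  with_seed(cfg$seed, {
    ## ---- genome & genes ----------------------------------------------
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    genome_chars <- lapply(chroms, function(ch) {
      sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    })
    names(genome_chars) <- chroms

    layout <- place_genes(cfg, plus_strand_first = 2 * cfg$n_sponge + 4)
    models <- gene_model_set(layout$genes, layout$exons)
    genes <- models$genes

    ## ---- role allocation ---------------------------------------------
    n_ex <- cfg$n_circ[["exonic"]]; n_in <- cfg$n_circ[["intronic"]]
    n_anti <- cfg$n_circ[["antisense"]]
    exon_counts <- table(models$exons$gene_id)
    eligible <- genes$gene_id[exon_counts[genes$gene_id] >= 3]
    plus_eligible <- genes$gene_id[genes$strand == "+" &
                                     genes$gene_id %in% eligible]
    if (length(plus_eligible) < cfg$n_sponge) {
      stop("not enough plus-strand multi-exon genes for sponge circRNAs")
    }
    sponge_hosts <- plus_eligible[seq_len(cfg$n_sponge)]
    other_hosts <- sample(setdiff(eligible, sponge_hosts))
    if (length(other_hosts) < n_ex - cfg$n_sponge + n_in + n_anti) {
      stop("not enough genes to host the requested circRNAs")
    }
    exonic_hosts <- c(sponge_hosts,
                      other_hosts[seq_len(n_ex - cfg$n_sponge)])
    rest <- setdiff(other_hosts, exonic_hosts)
    intronic_hosts <- rest[seq_len(n_in)]
    anti_hosts <- if (n_anti > 0) {
      rest[n_in + seq_len(n_anti)]
    } else {
      character(0)
    }
    host_genes <- c(exonic_hosts, intronic_hosts, anti_hosts)
    no_circ_pool <- setdiff(genes$gene_id, host_genes)
    if (length(no_circ_pool) < max(cfg$n_sponge, cfg$n_de_genes)) {
      stop("not enough circRNA-free genes for sponge targets / DE genes; ",
           "increase n_genes")
    }
    sponge_targets <- sample(no_circ_pool, cfg$n_sponge)

    ## ---- plant circRNAs ----------------------------------------------
    circ_rows <- list()
    add_circ <- function(chrom, start, end, strand, type, gene,
                         fl = c(NA, NA), fr = c(NA, NA)) {
      circ_rows[[length(circ_rows) + 1]] <<- data.frame(
        key = circ_key(chrom, start, end, strand), chrom = chrom,
        start = start, end = end, strand = strand, type = type,
        parental_gene = gene,
        flank_left_start = fl[1], flank_left_end = fl[2],
        flank_right_start = fr[1], flank_right_end = fr[2],
        stringsAsFactors = FALSE)
    }
    for (gid in exonic_hosts) {
      ex <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
      ex <- ex[order(ex$start), ]
      k <- nrow(ex)
      i <- if (k == 3) 2L else sample(2:(k - 1), 1)
      j <- min(k - 1, i + sample(0:1, 1))
      g <- genes[genes$gene_id == gid, ]
      add_circ(g$chrom, ex$start[i], ex$end[j], g$strand, "exonic", gid,
               fl = c(ex$end[i - 1], ex$start[i]),
               fr = c(ex$end[j], ex$start[j + 1]))
    }
    for (gid in intronic_hosts) {
      intr <- gene_introns(models, gid)
      intr <- intr[intr$end - intr$start >= 150, , drop = FALSE]
      if (!nrow(intr)) stop("intronic host without a usable intron")
      iv <- intr[sample(nrow(intr), 1), ]
      len <- iv$end - iv$start
      clen <- runif_int(1, c(80, min(len - 40, 600)))
      off <- runif_int(1, c(10, len - clen - 10))
      g <- genes[genes$gene_id == gid, ]
      add_circ(g$chrom, iv$start + off, iv$start + off + clen, g$strand,
               "intronic", gid)
    }
    for (gid in anti_hosts) {
      g <- genes[genes$gene_id == gid, ]
      span <- g$end - g$start
      clen <- runif_int(1, c(150, min(600, span - 20)))
      off <- runif_int(1, c(5, span - clen - 5))
      add_circ(g$chrom, g$start + off, g$start + off + clen,
               if (g$strand == "+") "-" else "+", "antisense", gid)
    }
    n_ig <- cfg$n_circ[["intergenic"]]
    if (n_ig > 0) {
      ## gaps between gene spans, per chromosome
      gaps <- do.call(rbind, lapply(chroms, function(ch) {
        g <- genes[genes$chrom == ch, ]
        g <- g[order(g$start), ]
        bounds <- c(0, as.vector(rbind(g$start, g$end)), cfg$chrom_length)
        starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ends <- bounds[seq(2, length(bounds), by = 2)]
        data.frame(chrom = ch, start = starts, end = ends,
                   stringsAsFactors = FALSE)
      }))
      gaps <- gaps[gaps$end - gaps$start >= 600, , drop = FALSE]
      picks <- sample(nrow(gaps), n_ig)
      for (p in picks) {
        gp <- gaps[p, ]
        len <- gp$end - gp$start
        clen <- runif_int(1, c(150, min(400, len - 200)))
        off <- runif_int(1, c(100, len - clen - 100))
        add_circ(gp$chrom, gp$start + off, gp$start + off + clen,
                 sample(c("+", "-"), 1), "intergenic", NA_character_)
      }
    }
    circs <- do.call(rbind, circ_rows)
    if (anyDuplicated(circs$key)) stop("duplicate planted circRNA keys")

    ## ---- DE assignment -----------------------------------------------
    sponge_circ_keys <- circs$key[match(sponge_hosts,
                                        circs$parental_gene)]
    extra_de <- setdiff(circs$key[circs$type == "exonic"],
                        sponge_circ_keys)
    de_circ_keys <- c(sponge_circ_keys,
                      extra_de[seq_len(cfg$n_de_circ - cfg$n_sponge)])
    n_up <- ceiling(5 / 8 * cfg$n_de_circ)
    circ_folds <- stats::setNames(rep(1, nrow(circs)), circs$key)
    circ_folds[de_circ_keys[seq_len(n_up)]] <- cfg$de_circ_fold
    if (cfg$n_de_circ > n_up) {
      circ_folds[de_circ_keys[(n_up + 1):cfg$n_de_circ]] <-
        1 / cfg$de_circ_fold
    }
    de_gene_ids <- c(sponge_targets,
                     sample(setdiff(no_circ_pool, sponge_targets),
                            max(0, cfg$n_de_genes - cfg$n_sponge)))
    gene_folds <- stats::setNames(rep(1, nrow(genes)), genes$gene_id)
    gene_folds[de_gene_ids] <- cfg$de_gene_fold

    ## ---- miRNAs and planted binding sites ----------------------------
    mirnas <- stats::setNames(
      vapply(seq_len(cfg$n_mirnas), function(i) random_dna(cfg$mirna_length),
             ""),
      sprintf("miR%03d", seq_len(cfg$n_mirnas)))
    sponge <- data.frame(circ = sponge_circ_keys,
                         mirna = names(mirnas)[seq_len(cfg$n_sponge)],
                         gene = sponge_targets, stringsAsFactors = FALSE)
    ## embed the reverse complement of each sponge miRNA across the
    ## back-splice junction of its circRNA (half before the junction,
    ## half after) and inside one exon of its target mRNA
    for (i in seq_len(nrow(sponge))) {
      site <- strsplit(revcomp(mirnas[[sponge$mirna[i]]]), "")[[1]]
      m <- length(site)
      h <- m %/% 2
      cc <- circs[circs$key == sponge$circ[i], ]
      genome_chars[[cc$chrom]][(cc$end - h + 1):cc$end] <- site[1:h]
      genome_chars[[cc$chrom]][(cc$start + 1):(cc$start + m - h)] <-
        site[(h + 1):m]
      ## mRNA site: middle of the largest exon of the target gene. For a
      ## minus-strand gene the transcript is the reverse complement of the
      ## genomic exon chain, so the genomic insert is reverse-complemented
      ## to make the site read correctly on the transcript.
      ex <- models$exons[models$exons$gene_id == sponge$gene[i], ,
                         drop = FALSE]
      ex <- ex[which.max(ex$end - ex$start), ]
      tgt_strand <- genes$strand[genes$gene_id == sponge$gene[i]]
      ins <- if (tgt_strand == "-") {
        strsplit(revcomp(paste(site, collapse = "")), "")[[1]]
      } else {
        site
      }
      mid <- (ex$start + ex$end) %/% 2
      genome_chars[[ex$chrom]][(mid + 1):(mid + m)] <- ins
    }

    ## ---- repeats ------------------------------------------------------
    flank_keys <- circs$type == "exonic"
    flanks <- rbind(
      data.frame(chrom = circs$chrom[flank_keys],
                 start = circs$flank_left_start[flank_keys],
                 end = circs$flank_left_end[flank_keys]),
      data.frame(chrom = circs$chrom[flank_keys],
                 start = circs$flank_right_start[flank_keys],
                 end = circs$flank_right_end[flank_keys]))
    flanks <- unique(flanks)
    flank_id <- paste(flanks$chrom, flanks$start, flanks$end)
    rep_rows <- list()
    intr_all <- models$introns
    for (i in seq_len(nrow(intr_all))) {
      iv <- intr_all[i, ]
      enriched <- paste(iv$chrom, iv$start, iv$end) %in% flank_id
      cov <- if (enriched) cfg$repeat_enrichment else cfg$repeat_background
      len <- iv$end - iv$start
      total <- round(cov * len)
      if (total < 20) next
      off <- runif_int(1, c(0, len - total))
      cls <- if (!enriched && stats::runif(1) < 0.35) {
        sample(c("LINE", "DNA"), 1)
      } else {
        "LTR"
      }
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        chrom = iv$chrom, start = iv$start + off,
        end = iv$start + off + total, class = cls,
        stringsAsFactors = FALSE)
    }
    repeats <- do.call(rbind, rep_rows)

    ## ---- methylation --------------------------------------------------
    genome_str <- vapply(genome_chars, paste, "", collapse = "")
    meth_rows <- lapply(chroms, function(ch) {
      chars <- genome_chars[[ch]]
      cpos <- which(chars == "C")
      cpos <- cpos[cpos <= length(chars) - 2]
      ## context from the two following bases
      nxt1 <- chars[cpos + 1]; nxt2 <- chars[cpos + 2]
      context <- ifelse(nxt1 == "G", "CpG",
                        ifelse(nxt2 == "G", "CHG", "CHH"))
      pos0 <- cpos - 1L
      fl <- flanks[flanks$chrom == ch, , drop = FALSE]
      elevated <- rep(FALSE, length(pos0))
      for (r in seq_len(nrow(fl))) {
        elevated <- elevated | (pos0 >= fl$start[r] & pos0 < fl$end[r])
      }
      mlevel <- ifelse(elevated, cfg$meth_elevation, cfg$meth_background)
      level <- stats::rbeta(length(pos0), mlevel * 10, (1 - mlevel) * 10)
      total <- stats::rpois(length(pos0), cfg$meth_coverage)
      keep <- total > 0
      methylated <- stats::rbinom(sum(keep), total[keep], level[keep])
      data.frame(chrom = ch, pos = pos0[keep], context = context[keep],
                 methylated = methylated, total = total[keep],
                 stringsAsFactors = FALSE)
    })
    meth <- methylation_track(do.call(rbind, meth_rows))

    ## ---- counts -------------------------------------------------------
    n_reps <- cfg$n_replicates
    samples <- paste0(rep(cfg$timepoints, each = n_reps), "_R",
                      seq_len(n_reps))
    circ_base <- stats::rlnorm(nrow(circs), log(cfg$mean_junction_reads),
                               0.5)
    circ_counts <- draw_count_matrix(circ_base, circ_folds[circs$key],
                                     cfg$timepoints, n_reps,
                                     cfg$dispersion, circs$key)
    gene_base <- stats::rlnorm(nrow(genes), log(cfg$gene_mean_reads), 0.7)
    gene_counts <- draw_count_matrix(gene_base, gene_folds[genes$gene_id],
                                     cfg$timepoints, n_reps,
                                     cfg$dispersion, genes$gene_id)
    lib_sizes <- stats::setNames(
      round(stats::runif(length(samples), 0.9e9, 1.1e9)), samples)

    ## ---- caller tables ------------------------------------------------
    n_shared <- round(cfg$caller_overlap_fraction * nrow(circs))
    shared_keys <- circs$key[seq_len(n_shared)]
    in_consensus <- circs$key %in% shared_keys
    make_decoys <- function(forbidden) {
      if (cfg$n_decoys_per_caller == 0) {
        return(data.frame(key = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE))
      }
      rows <- list()
      while (length(rows) < cfg$n_decoys_per_caller) {
        ch <- sample(chroms, 1)
        st <- runif_int(1, c(0, cfg$chrom_length - 2200))
        en <- st + runif_int(1, c(200, 2000))
        key <- circ_key(ch, st, en, "+")
        if (key %in% forbidden ||
            key %in% vapply(rows, function(r) r$key, "")) next
        rows[[length(rows) + 1]] <- data.frame(
          key = key, chrom = ch, start = st, end = en, strand = "+",
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    decoy_a <- make_decoys(circs$key)
    decoy_b <- make_decoys(c(circs$key, decoy_a$key))
    decoy_counts <- function(d) {
      draw_count_matrix(stats::rlnorm(nrow(d), log(10), 0.5),
                        rep(1, nrow(d)), cfg$timepoints, n_reps,
                        cfg$dispersion, d$key)
    }
    calls_a <- circ_calls(
      c(circs$chrom, decoy_a$chrom), c(circs$start, decoy_a$start),
      c(circs$end, decoy_a$end), c(circs$strand, decoy_a$strand),
      rbind(circ_counts, decoy_counts(decoy_a)), "callerA")
    b_keep <- in_consensus
    calls_b <- circ_calls(
      c(circs$chrom[b_keep], decoy_b$chrom),
      c(circs$start[b_keep], decoy_b$start),
      c(circs$end[b_keep], decoy_b$end),
      c(circs$strand[b_keep], decoy_b$strand),
      rbind(circ_counts[b_keep, , drop = FALSE], decoy_counts(decoy_b)),
      "callerB")

    ## ---- conservation subjects ----------------------------------------
    genome <- Biostrings::DNAStringSet(genome_str)
    names(genome) <- chroms
    cons_keys <- shared_keys[seq_len(min(cfg$n_conserved_subjects,
                                         length(shared_keys)))]
    species_pool <- c("speciesA", "speciesB", "speciesC")
    subj_seqs <- character(0); subj_species <- character(0)
    for (i in seq_along(cons_keys)) {
      js <- build_junction_sequence(
        circs[circs$key == cons_keys[i], ], genome)
      chars <- strsplit(js$seq, "")[[1]]
      n_mut <- round(cfg$subject_mutation_rate * length(chars))
      if (n_mut > 0) {
        at <- sample(length(chars), n_mut)
        chars[at] <- vapply(chars[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
      }
      nm <- sprintf("subj_cons_%02d", i)
      subj_seqs[nm] <- paste(chars, collapse = "")
      subj_species[nm] <- species_pool[(i - 1) %% 3 + 1]
    }
    for (i in seq_len(cfg$n_random_subjects)) {
      nm <- sprintf("subj_rand_%02d", i)
      subj_seqs[nm] <- random_dna(200)
      subj_species[nm] <- species_pool[(i - 1) %% 3 + 1]
    }

    ## ---- write files ---------------------------------------------------
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      gff3 = file.path(dir, "annotation.gff3"),
      repeats = file.path(dir, "repeats.bed"),
      methylation = file.path(dir, "methylation.tsv"),
      calls_a = file.path(dir, "caller_A.tsv"),
      calls_b = file.path(dir, "caller_B.tsv"),
      circ_counts = file.path(dir, "circ_counts.tsv"),
      gene_counts = file.path(dir, "gene_counts.tsv"),
      lib_sizes = file.path(dir, "lib_sizes.tsv"),
      mirnas = file.path(dir, "mirnas.fa"),
      subjects = file.path(dir, "subject_circs.fa"),
      subject_species = file.path(dir, "subject_species.tsv"),
      truth_circs = file.path(dir, "truth_circs.tsv"),
      truth_sponge = file.path(dir, "truth_sponge.tsv"),
      truth_de_genes = file.path(dir, "truth_de_genes.tsv"),
      truth_conserved = file.path(dir, "truth_conserved.tsv"),
      config = file.path(dir, "sim_config.txt")
    )
    write_fasta(genome, paths$genome)
    write_gff3(models, paths$gff3)
    write_bed(data.frame(chrom = repeats$chrom, start = repeats$start,
                         end = repeats$end, name = repeats$class),
              paths$repeats)
    write_methylation(meth, paths$methylation)
    write_circ_calls(calls_a, paths$calls_a)
    write_circ_calls(calls_b, paths$calls_b)
    write_count_matrix(circ_counts, paths$circ_counts)
    write_count_matrix(gene_counts, paths$gene_counts)
    utils::write.table(
      data.frame(sample = samples, clean_reads = lib_sizes),
      paths$lib_sizes, sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(mirnas, paths$mirnas)
    write_fasta(subj_seqs, paths$subjects)
    utils::write.table(
      data.frame(subject = names(subj_species), species = subj_species),
      paths$subject_species, sep = "\t", quote = FALSE, row.names = FALSE)
    truth_circs <- circs
    truth_circs$in_consensus <- in_consensus
    truth_circs$fold <- unname(circ_folds[circs$key])
    truth_circs$de <- truth_circs$fold != 1
    utils::write.table(truth_circs, paths$truth_circs, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sponge, paths$truth_sponge, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = de_gene_ids,
                 fold = unname(gene_folds[de_gene_ids])),
      paths$truth_de_genes, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(key = cons_keys), paths$truth_conserved,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste0(names(cfg), "=",
                      vapply(cfg, function(x) paste(x, collapse = ","), "")),
               paths$config)

    structure(list(paths = paths,
                   truth = list(circs = truth_circs, sponge = sponge,
                                de_genes = de_gene_ids,
                                conserved = cons_keys),
                   samples = samples, models = models, genome = genome,
                   mirnas = mirnas, lib_sizes = lib_sizes,
                   config = cfg),
              class = "sim_bundle")
  })
}
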