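## End-to-end orchestration: consensus -> classification -> conservation
## -> flanking features -> expression/DE -> sponge network, with a
## machine-readable report. Deterministic given (inputs, config, seed).

#' Pipeline run configuration
#'
#' @param calls_a,calls_b Paths to the two caller call tables.
#' @param genome Path to the genome FASTA.
#' @param gff3 Path to the gene annotation GFF3.
#' @param repeats Path to the repeat BED6 (optional; NULL skips repeat
#'   analysis).
#' @param methylation Path to the methylation TSV (optional; NULL skips
#'   the methylation section with a notice).
#' @param circ_counts,gene_counts Paths to count matrices (TSV).
#' @param lib_sizes Path to the library-size TSV.
#' @param mirnas Path to the mature miRNA FASTA (optional).
#' @param subjects Path to the conservation subject FASTA (optional).
#' @param subject_species Path to a subject->species TSV (optional).
#' @param seed Integer seed for the stochastic stages (background
#'   sampling).
#' @param min_junction_reads,max_length Consensus thresholds.
#' @param kmer_k k-mer length for conservation.
#' @param r_cutoff Conservation cutoff on Pearson r.
#' @param de_alpha,de_lfc circRNA differential-expression thresholds
#'   (raw p and |log2FC|).
#' @param gene_de_alpha Gene DE threshold on the BH-adjusted p.
#' @param max_expectation miRNA site expectation cutoff.
#' @param caller_names Labels for the two callers.
#' @return List of class `run_config`.
#' @export
run_config <- function(calls_a, calls_b, genome, gff3, repeats = NULL,
                       methylation = NULL, circ_counts = NULL,
                       gene_counts = NULL, lib_sizes = NULL, mirnas = NULL,
                       subjects = NULL, subject_species = NULL, seed,
                       min_junction_reads = 2, max_length = 10000,
                       kmer_k = 6, r_cutoff = 0.2, de_alpha = 0.05,
                       de_lfc = 1, gene_de_alpha = 0.05,
                       max_expectation = 5.0,
                       caller_names = c("callerA", "callerB")) {
  if (missing(seed)) stop("run_config requires a seed")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run configuration from a simulated bundle
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param seed Seed for the pipeline's stochastic stages (defaults to the
#'   bundle's simulation seed).
#' @param ... Threshold overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
run_config_from_bundle <- function(bundle, seed = bundle$config$seed, ...) {
  p <- bundle$paths
  run_config(calls_a = p$calls_a, calls_b = p$calls_b, genome = p$genome,
             gff3 = p$gff3, repeats = p$repeats,
             methylation = p$methylation, circ_counts = p$circ_counts,
             gene_counts = p$gene_counts, lib_sizes = p$lib_sizes,
             mirnas = p$mirnas, subjects = p$subjects,
             subject_species = p$subject_species, seed = seed, ...)
}

#' Run the full circRNA characterization pipeline
#'
#' Stages: consensus filtering, type classification, conservation
#' (junction alignment + k-mer), flanking-intron repeat/methylation
#' comparison against a sampled background, RPB expression and
#' differential expression (union of each treatment timepoint against the
#' reference), and sponge-network assembly. A missing methylation track
#' skips that section with an explicit notice rather than failing.
#'
#' @param config A [run_config()].
#' @return List of class `circ_report` with one element per stage plus
#'   `params` and `notices`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  notices <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## ---- inputs ---------------------------------------------------------
  calls_a <- stage("input", read_circ_calls(config$calls_a,
                                            config$caller_names[1]))
  calls_b <- stage("input", read_circ_calls(config$calls_b,
                                            config$caller_names[2]))
  genome <- stage("input", read_genome_fasta(config$genome))
  models <- stage("input", read_gff3(config$gff3))

  ## ---- consensus ------------------------------------------------------
  ov <- stage("consensus", overlap_stats(calls_a, calls_b))
  circs <- stage("consensus",
                 consensus_filter(calls_a, calls_b,
                                  config$min_junction_reads,
                                  config$max_length))

  ## ---- classification -------------------------------------------------
  classified <- stage("classify", classify_circs(circs, models))
  types <- type_summary(classified)
  ptable <- parental_gene_table(classified)

  ## ---- conservation ---------------------------------------------------
  conservation <- NULL
  if (!is.null(config$subjects)) {
    conservation <- stage("conserve", {
      subjects <- as.character(read_genome_fasta(config$subjects))
      species <- NULL
      if (!is.null(config$subject_species)) {
        sp <- utils::read.delim(config$subject_species,
                                stringsAsFactors = FALSE)
        species <- stats::setNames(sp$species, sp$subject)
      }
      jseqs <- build_junction_sequences(classified, genome)
      align_hits <- do.call(rbind, lapply(classified$key, function(k) {
        junction_conserved(list(key = k, seq = jseqs$seqs[[k]],
                                junction_offset = jseqs$offsets[[k]]),
                           subjects, species = species)
      }))
      kmer_hits <- kmer_conservation(jseqs$seqs, subjects,
                                     k = config$kmer_k,
                                     r_cutoff = config$r_cutoff)
      if (!is.null(species)) {
        kmer_hits$species <- species[kmer_hits$subject]
      }
      list(
        alignment = conservation_summary(align_hits, nrow(classified),
                                         "junction_covered"),
        kmer = conservation_summary(kmer_hits, nrow(classified),
                                    "conserved"),
        align_hits = align_hits, kmer_hits = kmer_hits
      )
    })
  } else {
    notices <- c(notices, "conservation skipped: no subject database")
  }

  ## ---- flanking features ----------------------------------------------
  exonic <- classified[classified$type == "exonic", , drop = FALSE]
  host_genes <- unique(stats::na.omit(classified$parental_gene[
    classified$type %in% c("exonic", "intronic")]))
  pool <- setdiff(models$genes$gene_id, host_genes)
  n_bg <- min(length(pool), length(host_genes))
  background <- sample_background(pool, n_bg, config$seed)

  flanks <- unique(rbind(
    data.frame(chrom = exonic$chrom, start = exonic$flank_left_start,
               end = exonic$flank_left_end),
    data.frame(chrom = exonic$chrom, start = exonic$flank_right_start,
               end = exonic$flank_right_end)))
  flanks <- flanks[!is.na(flanks$start), , drop = FALSE]
  bg_introns <- models$introns[models$introns$gene_id %in% background, ,
                               drop = FALSE]

  flanking <- list()
  gene_len <- function(ids) {
    g <- models$genes[match(ids, models$genes$gene_id), ]
    g$end - g$start
  }
  if (length(host_genes) >= 2 && length(background) >= 2) {
    flanking$gene_length <- stage("flanking",
      compare_groups(gene_len(host_genes), gene_len(background)))
    flanking$flank_intron_length <- stage("flanking",
      compare_groups(flanks$end - flanks$start,
                     bg_introns$end - bg_introns$start))
  }
  if (!is.null(config$repeats) && nrow(flanks) >= 2 &&
      nrow(bg_introns) >= 2) {
    repeats <- stage("input", read_repeats(config$repeats))
    rf <- function(df) {
      vapply(seq_len(nrow(df)), function(i) {
        repeat_fraction(df[i, , drop = FALSE], repeats)
      }, 0)
    }
    flanking$repeat_circ <- rf(flanks)
    flanking$repeat_background <- rf(bg_introns)
    flanking$repeat_comparison <- stage("flanking",
      compare_groups(flanking$repeat_circ, flanking$repeat_background,
                     log10_transform = FALSE))
    flanking$repeat_classes <- repeat_class_breakdown(flanks, repeats)
  }
  if (!is.null(config$methylation)) {
    meth <- stage("input", read_methylation(config$methylation))
    wm <- function(df) {
      vapply(seq_len(nrow(df)), function(i) {
        as.numeric(weighted_methylation(df[i, , drop = FALSE], meth))
      }, 0)
    }
    mc <- wm(flanks); mb <- wm(bg_introns)
    flanking$meth_circ <- mc
    flanking$meth_background <- mb
    if (sum(is.finite(mc)) >= 2 && sum(is.finite(mb)) >= 2) {
      flanking$meth_comparison <- stage("flanking",
        compare_groups(mc[is.finite(mc)], mb[is.finite(mb)],
                       log10_transform = FALSE))
    }
  } else {
    notices <- c(notices,
                 "methylation section skipped: no methylation track")
  }

  ## ---- expression ------------------------------------------------------
  expression <- NULL
  if (!is.null(config$circ_counts) && !is.null(config$lib_sizes)) {
    expression <- stage("express", {
      counts <- read_count_matrix(config$circ_counts)
      ls <- read_lib_sizes(config$lib_sizes)
      tps <- unique(sub("_R[0-9]+$", "", colnames(counts)))
      ref <- tps[1]
      dec <- de_timecourse(counts, ls, setdiff(tps, ref), ref,
                           alpha = config$de_alpha,
                           lfc_threshold = config$de_lfc)
      mean_rpb <- rowMeans(rpb_matrix(counts, ls[colnames(counts)]))
      list(reference = ref,
           bins = table(bin_expression(mean_rpb)),
           de = dec$combined,
           n_up = sum(dec$combined$direction == "up"),
           n_down = sum(dec$combined$direction == "down"))
    })
  }
  gene_de <- NULL
  if (!is.null(config$gene_counts) && !is.null(config$lib_sizes)) {
    gene_de <- stage("express", {
      counts <- read_count_matrix(config$gene_counts)
      ls <- read_lib_sizes(config$lib_sizes)
      tps <- unique(sub("_R[0-9]+$", "", colnames(counts)))
      dec <- de_timecourse(counts, ls, setdiff(tps, tps[1]), tps[1],
                           alpha = config$gene_de_alpha,
                           lfc_threshold = config$de_lfc,
                           use_adjusted_p = TRUE)
      dec$combined
    })
  }

  ## ---- sponge network --------------------------------------------------
  network <- NULL
  if (!is.null(config$mirnas) && !is.null(expression) &&
      !is.null(gene_de)) {
    network <- stage("network", {
      mirnas <- as.character(read_genome_fasta(config$mirnas))
      de_circ_keys <- expression$de$id[expression$de$direction != "ns"]
      de_gene_ids <- gene_de$id[gene_de$direction != "ns"]
      jseqs <- build_junction_sequences(
        classified[classified$key %in% de_circ_keys, , drop = FALSE],
        genome)
      csites <- do.call(rbind, lapply(names(jseqs$seqs), function(k) {
        circ_sites_on_junction(
          list(key = k, seq = jseqs$seqs[[k]],
               junction_offset = jseqs$offsets[[k]]),
          mirnas, max_expectation = config$max_expectation)
      }))
      if (is.null(csites)) {
        csites <- data.frame(target = character(), mirna = character(),
                             expectation = numeric())
      }
      mseqs <- stats::setNames(
        lapply(de_gene_ids, function(g)
          spliced_sequence(genome, models, g)),
        de_gene_ids)
      msites <- mrna_sites(unlist(mseqs), mirnas,
                           max_expectation = config$max_expectation)
      net <- build_network(de_circ_keys, de_gene_ids, csites, msites)
      list(network = net, circ_sites = csites, gene_sites = msites)
    })
  }

  report <- list(
    params = config[!vapply(config, is.null, TRUE)],
    callers = ov,
    n_consensus = nrow(classified),
    types = types,
    parental = list(n_genes = nrow(ptable), n_multi = sum(ptable$multi)),
    conservation = conservation[c("alignment", "kmer")],
    flanking = flanking[setdiff(names(flanking),
                                c("repeat_circ", "repeat_background",
                                  "meth_circ", "meth_background"))],
    expression = expression[c("reference", "bins", "n_up", "n_down")],
    network = if (!is.null(network)) network$network$counts,
    notices = notices
  )
  class(report) <- "circ_report"
  list(report = report, classified = classified, parental = ptable,
       conservation = conservation, flanking = flanking,
       expression = expression, gene_de = gene_de, network = network)
}

#' Write a pipeline report as JSON and Markdown
#'
#' @param result Return value of [run_all()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- result$report
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")
  ser <- rep
  ser$params <- lapply(ser$params, function(x)
    if (is.character(x) || is.numeric(x)) x else as.character(x))
  class(ser) <- NULL
  jsonlite::write_json(ser, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  lines <- c(
    "# circRNA characterization report", "",
    sprintf("- caller A calls: %d; caller B calls: %d; shared: %d; Jaccard: %.4f",
            rep$callers$n_a, rep$callers$n_b, rep$callers$n_shared,
            rep$callers$jaccard),
    sprintf("- high-confidence circRNAs: %d", rep$n_consensus),
    "", "## Types", "",
    sprintf("- %s: %d (%.1f%%)", rep$types$type, rep$types$n,
            rep$types$pct),
    "",
    sprintf("- parental genes: %d (%d with >= 2 circRNAs)",
            rep$parental$n_genes, rep$parental$n_multi)
  )
  if (!is.null(rep$expression)) {
    lines <- c(lines, "", "## Differential expression", "",
               sprintf("- up: %d; down: %d (vs %s)",
                       rep$expression$n_up, rep$expression$n_down,
                       rep$expression$reference))
  }
  if (!is.null(rep$network)) {
    lines <- c(lines, "", "## Sponge network", "",
               sprintf("- circRNAs: %d; miRNAs: %d; mRNAs: %d; edges: %d",
                       rep$network[["n_circ"]], rep$network[["n_mirna"]],
                       rep$network[["n_mrna"]], rep$network[["n_edges"]]))
  }
  if (length(rep$notices)) {
    lines <- c(lines, "", "## Notices", "", paste0("- ", rep$notices))
  }
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}
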