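## Expression quantification and differential expression of junction-read
## counts. The differential test is a two-sided exact negative-binomial
## test on group sums at equalized library sizes, with a common dispersion
## estimated by the method of moments — appropriate for the overdispersed,
## low-count nature of back-splice junction reads.

#' Junction reads per billion clean reads (RPB)
#'
#' @param junction_reads Junction read count(s).
#' @param clean_reads Total clean sequencing reads of the sample.
#' @return `junction_reads / (clean_reads / 1e9)`.
#' @export
rpb <- function(junction_reads, clean_reads) {
  if (any(clean_reads <= 0)) stop("clean_reads must be positive")
  if (any(junction_reads < 0)) stop("negative junction reads")
  junction_reads / (clean_reads / 1e9)
}

#' RPB matrix from counts and library sizes
#'
#' @param counts Matrix of junction reads (features x samples).
#' @param lib_sizes Clean reads per sample (length = ncol(counts)).
#' @return Matrix of RPB values.
#' @export
rpb_matrix <- function(counts, lib_sizes) {
  if (length(lib_sizes) != ncol(counts)) {
    stop("lib_sizes length must match sample columns")
  }
  sweep(counts, 2, lib_sizes / 1e9, "/")
}

#' Bin an RPB value into expression classes
#'
#' low: RPB < 100; medium: 100 <= RPB <= 500; high: RPB > 500.
#'
#' @param rpb_value Numeric vector of RPB values (>= 0).
#' @return Ordered factor with levels low < medium < high.
#' @export
bin_expression <- function(rpb_value) {
  if (any(rpb_value < 0)) stop("RPB must be non-negative")
  lab <- ifelse(rpb_value < 100, "low",
                ifelse(rpb_value <= 500, "medium", "high"))
  factor(lab, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Fragments per kilobase of exon model per million mapped fragments
#'
#' @param fragment_count Fragment count(s).
#' @param exonic_length_bp Summed exon length of the gene model (bp).
#' @param total_mapped Total mapped fragments in the sample.
#' @return FPKM value(s).
#' @export
fpkm <- function(fragment_count, exonic_length_bp, total_mapped) {
  if (any(exonic_length_bp <= 0)) stop("exonic length must be positive")
  if (any(total_mapped <= 0)) stop("total mapped fragments must be positive")
  fragment_count / (exonic_length_bp / 1000 * total_mapped / 1e6)
}

## ---- exact negative-binomial differential test -----------------------

## two-sided exact test on group sums: conditional on the total, sum the
## probabilities of all splits no more likely than the observed one.
exact_nb_p <- function(ya, yb, na, nb, phi) {
  total <- ya + yb
  if (total == 0) return(1)
  mu <- total / (na + nb)
  size_a <- na / phi
  size_b <- nb / phi
  k <- 0:total
  if (total > 20000) {
    lo <- stats::qnbinom(1e-14, mu = na * mu, size = size_a)
    hi <- stats::qnbinom(1e-14, mu = na * mu, size = size_a,
                         lower.tail = FALSE)
    k <- max(0, min(lo, ya)):min(total, max(hi, ya))
  }
  p_k <- stats::dnbinom(k, mu = na * mu, size = size_a) *
    stats::dnbinom(total - k, mu = nb * mu, size = size_b)
  denom <- sum(p_k)
  if (denom == 0) return(1)
  p_obs <- p_k[match(ya, k)]
  min(1, sum(p_k[p_k <= p_obs * (1 + 1e-10)]) / denom)
}

## Poisson fallback for single-replicate groups: conditional binomial test
exact_pois_p <- function(ya, yb, na, nb) {
  total <- ya + yb
  if (total == 0) return(1)
  p_k <- stats::dbinom(0:total, total, na / (na + nb))
  p_obs <- p_k[ya + 1]
  min(1, sum(p_k[p_k <= p_obs * (1 + 1e-10)]))
}

## method-of-moments common dispersion on normalized counts
estimate_common_dispersion <- function(norm_counts, groups) {
  phis <- apply(norm_counts, 1, function(y) {
    mus <- tapply(y, groups, mean)
    vars <- tapply(y, groups, stats::var)
    ns <- tapply(y, groups, length)
    mu <- mean(mus)
    if (mu <= 0) return(NA_real_)
    s2 <- sum(vars * (ns - 1)) / sum(ns - 1)
    (s2 - mu) / mu^2
  })
  max(mean(phis, na.rm = TRUE), 1e-4)
}

#' Differential expression by exact negative-binomial test
#'
#' Counts are normalized to the geometric-mean library size, a common
#' dispersion is estimated by the method of moments (floored at 1e-4), and
#' each feature is tested by a two-sided exact NB test comparing the group
#' sums of the (rounded) normalized counts. With a single replicate per
#' group the test falls back to a Poisson (conditional binomial) exact
#' test with a warning. P-values are Benjamini-Hochberg adjusted.
#'
#' @param counts Integer matrix, features x samples, with column names.
#' @param lib_sizes Named (or positionally matched) library sizes.
#' @param group_a,group_b Character vectors of column names for the two
#'   groups (a = treatment, b = reference).
#' @param alpha Significance level on the p-value column used for calling
#'   direction (default 0.05).
#' @param lfc_threshold Log2 fold-change magnitude required to call a
#'   feature up/down (default 1).
#' @param use_adjusted_p Call direction on the BH-adjusted p-value instead
#'   of the raw p-value (gene-style rule; default FALSE = circRNA-style).
#' @param dispersion Optional fixed common dispersion (skips estimation).
#' @return `data.frame` with `id`, `log2fc` (a vs b, pseudocount 0.5 on
#'   the normalized scale), `p`, `padj`, `direction` (up/down/ns).
#' @export
de_test <- function(counts, lib_sizes, group_a, group_b, alpha = 0.05,
                    lfc_threshold = 1, use_adjusted_p = FALSE,
                    dispersion = NULL) {
  if (!all(c(group_a, group_b) %in% colnames(counts))) {
    stop("group columns absent from count matrix")
  }
  if (!is.null(names(lib_sizes))) {
    lib_sizes <- lib_sizes[colnames(counts)]
  }
  cols <- c(group_a, group_b)
  groups <- rep(c("a", "b"), c(length(group_a), length(group_b)))
  ls <- lib_sizes[match(cols, colnames(counts))]
  l_ref <- exp(mean(log(ls)))
  norm <- sweep(counts[, cols, drop = FALSE], 2, l_ref / ls, "*")

  na <- length(group_a); nb <- length(group_b)
  single_rep <- na < 2 || nb < 2
  if (single_rep) {
    warning("fewer than 2 replicates in a group; Poisson exact fallback")
  }
  phi <- if (single_rep) NA_real_
         else if (!is.null(dispersion)) dispersion
         else estimate_common_dispersion(norm, groups)

  ya <- round(rowSums(norm[, groups == "a", drop = FALSE]))
  yb <- round(rowSums(norm[, groups == "b", drop = FALSE]))
  p <- vapply(seq_along(ya), function(i) {
    if (single_rep) exact_pois_p(ya[i], yb[i], na, nb)
    else exact_nb_p(ya[i], yb[i], na, nb, phi)
  }, 0)
  mean_a <- rowMeans(norm[, groups == "a", drop = FALSE])
  mean_b <- rowMeans(norm[, groups == "b", drop = FALSE])
  log2fc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  padj <- stats::p.adjust(p, method = "BH")
  p_call <- if (use_adjusted_p) padj else p
  direction <- ifelse(p_call <= alpha & log2fc > lfc_threshold, "up",
                      ifelse(p_call <= alpha & log2fc < -lfc_threshold,
                             "down", "ns"))
  out <- data.frame(id = rownames(counts), log2fc = log2fc, p = p,
                    padj = padj, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  out
}

#' Union of pairwise differential calls against a reference timepoint
#'
#' Runs [de_test()] for each treatment timepoint against the reference and
#' takes, per feature, the call with the smallest p-value.
#'
#' @param counts Count matrix with columns named `timepoint_Rrep`.
#' @param lib_sizes Library sizes per sample.
#' @param timepoints Character vector of treatment timepoints.
#' @param reference Reference timepoint (default first column group).
#' @param ... Passed to [de_test()].
#' @return List with `per_comparison` (named list of [de_test()] tables)
#'   and `combined` (per-feature best call with `comparison` column).
#' @export
de_timecourse <- function(counts, lib_sizes, timepoints, reference, ...) {
  sample_tp <- sub("_R[0-9]+$", "", colnames(counts))
  ref_cols <- colnames(counts)[sample_tp == reference]
  per <- lapply(timepoints, function(tp) {
    de_test(counts, lib_sizes, colnames(counts)[sample_tp == tp],
            ref_cols, ...)
  })
  names(per) <- timepoints
  combined <- NULL
  for (tp in timepoints) {
    d <- per[[tp]]
    d$comparison <- paste0(tp, "_vs_", reference)
    combined <- if (is.null(combined)) d else {
      better <- d$p < combined$p
      combined[better, ] <- d[better, ]
      combined
    }
  }
  list(per_comparison = per, combined = combined)
}

#' Hypergeometric term enrichment
#'
#' One-sided (upper tail) hypergeometric test per term with
#' Benjamini-Hochberg adjustment; the flat analogue of a GO
#' over-representation analysis with the term map taken as given.
#'
#' @param study_ids Study set (e.g. DE parental genes); must be a subset
#'   of `population_ids`.
#' @param population_ids Population (background) set.
#' @param term_map `data.frame` with columns `id`, `term`.
#' @param alpha Significance level applied to the adjusted p (reported as
#'   the `significant` column).
#' @return `data.frame` with `term`, `k` (study hits), `K` (population
#'   hits), `n` (study size), `N` (population size), `p`, `padj`,
#'   `significant`.
#' @export
hypergeom_enrich <- function(study_ids, population_ids, term_map,
                             alpha = 0.05) {
  study <- unique(study_ids)
  pop <- unique(population_ids)
  if (!all(study %in% pop)) {
    stop("study set is not a subset of the population")
  }
  term_map <- term_map[term_map$id %in% pop, , drop = FALSE]
  terms <- unique(term_map$term)
  N <- length(pop); n <- length(study)
  rows <- lapply(terms, function(tm) {
    ids <- unique(term_map$id[term_map$term == tm])
    K <- length(ids)
    k <- length(intersect(ids, study))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      padj = numeric(), significant = logical()))
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$padj <= alpha
  rownames(out) <- NULL
  out
}
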