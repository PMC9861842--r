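test_that("junction sequences join circle end to circle start", {
  genome <- toy_genome(3000)
  chr <- as.character(genome[[1]])
  circ <- data.frame(key = "chr1:1000|1400:+", chrom = "chr1",
                     start = 1000, end = 1400, strand = "+")
  js <- build_junction_sequence(circ, genome)
  expect_equal(js$junction_offset, 100)
  expect_equal(js$seq, paste0(substr(chr, 1301, 1400),
                              substr(chr, 1001, 1100)))

  # short circle: both segments capped at the circle length
  short <- data.frame(key = "chr1:100|150:+", chrom = "chr1",
                      start = 100, end = 150, strand = "+")
  js2 <- build_junction_sequence(short, genome)
  expect_equal(nchar(js2$seq), 100)
  expect_equal(js2$junction_offset, 50)
  expect_equal(js2$seq,
               paste0(substr(chr, 101, 150), substr(chr, 101, 150)))

  expect_error(build_junction_sequence(
    data.frame(key = "chrX:1|10:+", chrom = "chrX", start = 1, end = 10,
               strand = "+"), genome), "missing chromosome")
})

test_that("minus-strand junction sequences are built from the circle RC", {
  g <- Biostrings::DNAStringSet("TTACGTGCTT")
  names(g) <- "chr1"
  # circle [2,8) covers genomic ACGTGC; transcript = reverse complement
  circ <- data.frame(key = "chr1:2|8:-", chrom = "chr1", start = 2,
                     end = 8, strand = "-")
  js <- build_junction_sequence(circ, g)
  rc <- revcomp("ACGTGC")          # worked by hand: GCACGT
  expect_equal(rc, "GCACGT")
  expect_equal(js$seq, paste0(rc, rc))
  expect_equal(js$junction_offset, 6)
})

test_that("k-mer profiles match a sliding-window oracle", {
  set.seed(41)
  seqs <- vapply(1:2, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""), "")
  names(seqs) <- c("s1", "s2")
  k <- 3  # small k keeps the oracle exhaustive
  counts <- kmer_counts(seqs, k = k)
  oracle_counts <- function(s) {
    kmers <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    all_k <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1],
                   1, paste, collapse = "")
    table(factor(kmers, levels = sort(all_k))) / (nchar(s) / 1000)
  }
  for (i in 1:2) {
    o <- oracle_counts(seqs[i])
    expect_equal(unname(counts[i, names(o)]), unname(as.numeric(o)))
  }

  # textbook Pearson on standardized vectors equals kmer_pearson
  z <- standardize_profiles(counts)
  r_oracle <- {
    a <- z[1, ]; b <- z[2, ]
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  expect_equal(kmer_pearson(z[1, ], z[2, ])$r, r_oracle)
  expect_equal(kmer_pearson(z[1, ], z[1, ])$r, 1.0)
})

test_that("the k-mer conservation call is strictly greater than the cutoff", {
  # a self-correlation of exactly 1 at a cutoff of 1 must not be called
  # conserved: the rule is strictly greater-than
  a <- c(2, 1, -1, -2)
  expect_identical(stats::cor(a, a), 1)
  expect_false(kmer_pearson(a, a, r_cutoff = 1)$conserved)
  # just below the correlation, the call flips on
  b <- c(2, -2, -1, 1)   # cor(a, b) = 1/10
  expect_false(kmer_pearson(a, b, r_cutoff = 0.1)$conserved)
  expect_true(kmer_pearson(a, b, r_cutoff = 0.09)$conserved)
  # zero-variance profile is undefined, flagged, not conserved
  flat <- kmer_pearson(rep(1, 4), a)
  expect_true(is.nan(flat$r))
  expect_true(flat$undefined)
})

test_that("k-mer profiles are nearly invariant to self-concatenation", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  k <- 6
  p1 <- kmer_counts(c(x = s), k = k)
  p2 <- kmer_counts(c(x = paste0(s, s)), k = k)
  # only the k-1 junction k-mers differ; per-kb counts shift by < 2k/L
  expect_lt(max(abs(p1 - p2)), 2 * k / (nchar(s) / 1000) / k)
})

test_that("junction alignment agrees with a Smith-Waterman oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(43)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (i in 1:12) {
    L1 <- sample(60:200, 1)
    a <- paste(sample(c("A", "C", "G", "T"), L1, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(60:200, 1), TRUE),
               collapse = "")
    if (i %% 2 == 0) b <- paste0(substr(a, 5, min(L1, 150)), b)
    mine <- circscape:::sw_local(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 5, gapExtension = 2)
    expect_equal(mine$score, max(Biostrings::score(ref), 0))
  }
})

test_that("junction-covered hits require alignment across the junction", {
  genome <- toy_genome(4000, seed = 44)
  circ <- data.frame(key = "chr1:1000|1600:+", chrom = "chr1",
                     start = 1000, end = 1600, strand = "+")
  js <- build_junction_sequence(circ, genome)

  # exact copy: one hit covering the junction at 100% identity
  hits <- junction_conserved(js, c(self = js$seq))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 100)
  expect_true(hits$junction_covered)

  # junction region replaced by random bases: flank can still align but
  # no hit may cover the junction
  set.seed(45)
  broken <- js$seq
  substr(broken, 61, 140) <- paste(sample(c("A", "C", "G", "T"), 80, TRUE),
                                   collapse = "")
  hits2 <- junction_conserved(js, c(broken = broken))
  expect_true(nrow(hits2) == 0 || !any(hits2$junction_covered))

  # subject matching only query positions 1..80: hit exists but the
  # junction is not covered, so it is excluded from the conserved count
  left_only <- substr(js$seq, 1, 80)
  hits3 <- junction_conserved(js, c(lo = left_only))
  expect_equal(nrow(hits3), 1)
  expect_false(hits3$junction_covered)
  expect_equal(conservation_summary(hits3, 1)$n_conserved, 0)

  expect_error(junction_conserved(list(key = "q", seq = "ACGTACGT",
                                       junction_offset = 4),
                                  c(s = js$seq)), "seed word")
})

test_that("conserved fractions follow from unique conserved queries", {
  hits <- data.frame(query = sprintf("c%04d", 1:655),
                     species = "speciesA",
                     junction_covered = TRUE)
  s <- conservation_summary(hits, 2702)
  expect_equal(s$n_conserved, 655)
  expect_equal(round(s$fraction, 1), 24.2)

  expect_equal(conservation_summary(hits[0, ], 100)$fraction, 0)
  all_hits <- data.frame(query = sprintf("c%d", 1:10),
                         species = "speciesB", junction_covered = TRUE)
  expect_equal(conservation_summary(all_hits, 10)$fraction, 100)
  expect_error(conservation_summary(all_hits, 0), "positive")
})
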