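# Shared in-code fixtures: a three-exon toy gene model, a deterministic
# random genome, and small caller tables.

toy_models <- function() {
  gene_model_set(
    genes = data.frame(
      gene_id = c("G1", "G2"),
      chrom = c("chr1", "chr1"),
      strand = c("+", "-"),
      stringsAsFactors = FALSE
    ),
    exons = data.frame(
      gene_id = c("G1", "G1", "G1", "G2", "G2"),
      start = c(100, 300, 500, 2000, 2500),
      end = c(200, 400, 600, 2200, 2800),
      stringsAsFactors = FALSE
    )
  )
}

toy_genome <- function(len = 5000, seed = 99, chrom = "chr1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- chrom
  g
}

toy_calls <- function(keys, reads, caller = "X",
                      samples = c("CK_R1", "C6_R1")) {
  kd <- parse_circ_key(keys)
  mat <- matrix(rep(reads, each = length(samples)),
                ncol = length(samples), byrow = TRUE,
                dimnames = list(NULL, samples))
  circ_calls(kd$chrom, kd$start, kd$end, kd$strand, mat, caller)
}

# a small, fast simulation configuration for pipeline-level tests
small_sim_config <- function(seed) {
  sim_config(seed = seed, n_genes = 32, chrom_length = 140000,
             n_circ = c(exonic = 14, intronic = 4, intergenic = 2,
                        antisense = 1),
             n_de_circ = 5, n_sponge = 3, n_de_genes = 8, n_mirnas = 5,
             n_decoys_per_caller = 6, n_conserved_subjects = 3,
             n_random_subjects = 6)
}
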