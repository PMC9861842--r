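test_that("GFF3 ingest converts coordinates and derives introns", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=GA",
    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=GA.t1;Parent=GA",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tID=e1;Parent=GA.t1",
    "chr1\tsrc\texon\t301\t400\t.\t+\t.\tID=e2;Parent=GA.t1"
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  models <- read_gff3(path)
  ex <- models$exons[models$exons$gene_id == "GA", ]
  # 1-based closed [101,200] becomes 0-based half-open [100,200)
  expect_equal(ex$start, c(100, 300))
  expect_equal(ex$end, c(200, 400))
  intr <- gene_introns(models, "GA")
  expect_equal(intr$start, 200)
  expect_equal(intr$end, 300)
  # exon + intron lengths tile the gene span exactly
  g <- models$genes[models$genes$gene_id == "GA", ]
  expect_equal(sum(ex$end - ex$start) + sum(intr$end - intr$start),
               g$end - g$start)
})

test_that("multi-transcript genes collapse to the longest exon chain", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=GB",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=GB.t1;Parent=GB",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=x1;Parent=GB.t1",
    "chr1\tsrc\texon\t201\t300\t.\t+\t.\tID=x2;Parent=GB.t1",
    "chr1\tsrc\texon\t801\t1000\t.\t+\t.\tID=x3;Parent=GB.t1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=GB.t2;Parent=GB",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tID=y1;Parent=GB.t2",
    "chr1\tsrc\texon\t401\t500\t.\t+\t.\tID=y2;Parent=GB.t2"
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  models <- read_gff3(path)
  ex <- models$exons[models$exons$gene_id == "GB", ]
  # t1 has 3 exons totalling 400 bp vs t2's 200 bp
  expect_equal(nrow(ex), 3)
  expect_equal(ex$end[3], 1000)
})

test_that("malformed GFF3 reports the offending line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=G",
               "chr1\tsrc\texon\t1\t100"), path)
  expect_error(read_gff3(path), "line 3")
})

test_that("exon outside its gene span is rejected", {
  gff <- c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=GC",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=GC.t1;Parent=GC",
    "chr1\tsrc\texon\t101\t250\t.\t+\t.\tID=z1;Parent=GC.t1"
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  expect_error(read_gff3(path), "outside gene span")
})

test_that("caller call tables normalize keys and merge duplicates", {
  mat <- matrix(c(3, 1), nrow = 1, dimnames = list(NULL, c("s1", "s2")))
  calls <- circ_calls("chr1", 100, 500, "+", mat, "toolX")
  expect_equal(calls$key, "chr1:100|500:+")
  expect_equal(unname(calls$reads[1, "s1"]), 3)

  dup <- circ_calls(c("chr1", "chr1"), c(100, 100), c(500, 500),
                    c("+", "+"),
                    matrix(c(2, 0, 3, 1), nrow = 2, byrow = TRUE,
                           dimnames = list(NULL, c("s1", "s2"))), "toolX")
  expect_equal(nrow(dup), 1)
  expect_equal(unname(dup$reads[1, ]), c(5, 1))

  expect_error(circ_calls("chr1", 500, 100, "+", mat, "t"), "end <= start")
  expect_error(circ_calls("chr1", 100, 500, "+",
                          matrix(-1, 1, 1, dimnames = list(NULL, "s1")),
                          "t"), "negative")
})

test_that("call tables round-trip through TSV", {
  calls <- toy_calls(c("chr1:10|200:+", "chr2:5|900:-"), c(4, 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_circ_calls(calls, path)
  back <- read_circ_calls(path, "X")
  expect_equal(back$key, calls$key)
  expect_equal(back$reads, calls$reads)
})

test_that("methylation track validates and round-trips", {
  df <- data.frame(chrom = "chr1", pos = c(50, 60), context = "CpG",
                   methylated = c(3, 10), total = c(10, 10))
  tr <- methylation_track(df)
  expect_s3_class(tr, "methylation_track")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_methylation(tr, path)
  back <- read_methylation(path)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  df$methylated[1] <- 11
  expect_error(methylation_track(df), "exceeds total")

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(read_methylation(empty)), 0)
})

test_that("BED and FASTA writers round-trip", {
  iv <- data.frame(chrom = rep("chr1", 10),
                   start = seq(0, 900, by = 100),
                   end = seq(50, 950, by = 100),
                   name = rep(c("LTR", "LINE"), 5))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path)
  back <- read_repeats(path)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$class, iv$name)

  fa <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(a = "ACGT", b = "GGGTTTAA")
  write_fasta(seqs, fa)
  expect_equal(as.character(read_genome_fasta(fa)), seqs)
})

test_that("spliced transcript sequence respects strand", {
  models <- toy_models()
  genome <- toy_genome()
  s_plus <- spliced_sequence(genome, models, "G1")
  expect_equal(nchar(s_plus), 300)
  chr <- as.character(genome[[1]])
  expect_equal(s_plus, paste0(substr(chr, 101, 200), substr(chr, 301, 400),
                              substr(chr, 501, 600)))
  s_minus <- spliced_sequence(genome, models, "G2")
  expect_equal(s_minus,
               revcomp(paste0(substr(chr, 2001, 2200),
                              substr(chr, 2501, 2800))))
})
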