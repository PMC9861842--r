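mk_mirna <- function(seed = 71, len = 21) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

embed_site <- function(mirna, flank_left = 60, flank_right = 60,
                       seed = 72) {
  set.seed(seed)
  paste0(paste(sample(c("A", "C", "G", "T"), flank_left, TRUE),
               collapse = ""),
         revcomp(mirna),
         paste(sample(c("A", "C", "G", "T"), flank_right, TRUE),
               collapse = ""))
}

test_that("a perfect complement scores expectation 0 at its position", {
  mir <- mk_mirna()
  target <- embed_site(mir)
  sites <- predict_sites(mir, target)
  hit <- sites[sites$expectation == 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$target_start, 60)
  expect_equal(hit$n_mismatch, 0)
  expect_equal(hit$n_gap, 0)
})

test_that("penalties follow the position-weighted scheme", {
  mir <- mk_mirna()
  m <- nchar(mir)
  site <- strsplit(revcomp(mir), "")[[1]]

  # mismatch at miRNA position 10 (inside the 2-13 seed region): 1.0 x 2.
  # rc index of miRNA position p is m - p + 1.
  j <- m - 10 + 1
  mm <- site
  # choose a base that is neither the complement nor a G:U partner
  mm[j] <- setdiff(c("A", "C", "G", "T"),
                   c(site[j],
                     if (site[j] == "C") "T" else character(0),
                     if (site[j] == "A") "G" else character(0)))[1]
  target <- paste(mm, collapse = "")
  s <- predict_sites(mir, target)
  expect_equal(s$expectation[s$target_start == 0 & s$n_gap == 0], 2.0)

  # G:U wobble at miRNA position 20 (outside the seed region): 0.5.
  # force miRNA position 20 to G so the wobble pairs G with target T
  mir2 <- mir
  substr(mir2, 20, 20) <- "G"
  site2 <- strsplit(revcomp(mir2), "")[[1]]
  j2 <- m - 20 + 1
  expect_equal(site2[j2], "C")
  site2[j2] <- "T"
  s2 <- predict_sites(mir2, paste(site2, collapse = ""))
  row <- s2[s2$target_start == 0 & s2$n_gap == 0, ]
  expect_equal(row$expectation, 0.5)
  expect_equal(row$n_gu, 1)
})

test_that("expectation is 0 iff perfect and grows under any single edit", {
  mir <- mk_mirna(seed = 73)
  m <- nchar(mir)
  site <- strsplit(revcomp(mir), "")[[1]]
  base <- predict_sites(mir, paste(site, collapse = ""))
  expect_equal(min(base$expectation), 0)
  for (j in c(1, 5, 12, m)) {
    edited <- site
    edited[j] <- setdiff(c("A", "C", "G", "T"), edited[j])[1]
    s <- predict_sites(mir, paste(edited, collapse = ""),
                       max_expectation = 10)
    ungapped <- s[s$target_start == 0 & s$n_gap == 0, ]
    if (nrow(ungapped)) expect_gt(ungapped$expectation, 0)
  }
})

test_that("alphabet and length contracts are enforced", {
  expect_error(predict_sites("ACGTACGTACGTACGTACGUX", "ACGT"), "alphabet")
  expect_error(predict_sites(mk_mirna(), "ACGT"), "shorter")
  expect_error(predict_sites("ACGT", "ACGTACGTACGT"), "18-24")
})

test_that("junction-spanning sites are found on the junction sequence", {
  mir <- mk_mirna(seed = 74)
  m <- nchar(mir)
  site <- revcomp(mir)
  set.seed(75)
  left <- paste(sample(c("A", "C", "G", "T"), 100 - 10, TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 100 - (m - 10), TRUE),
                 collapse = "")
  jseq <- paste0(left, site, right)   # junction offset 100 splits the site
  junction <- list(key = "c1", seq = jseq, junction_offset = 100)
  sites <- circ_sites_on_junction(junction, c(mirX = mir),
                                  max_expectation = 0)
  expect_equal(nrow(sites), 1)
  expect_true(sites$junction_spanning)

  # detection on the circular junction sequence is a superset of
  # detection on the two linear flanks
  flank_hits <- rbind(
    predict_sites(mir, substr(jseq, 1, 100), max_expectation = 0),
    predict_sites(mir, substr(jseq, 101, 200), max_expectation = 0))
  expect_equal(nrow(flank_hits), 0)

  # a site entirely within one flank is identical to the linear call
  jseq2 <- paste0(site, paste(sample(c("A", "C", "G", "T"), 179, TRUE),
                              collapse = ""))
  junction2 <- list(key = "c2", seq = jseq2, junction_offset = 100)
  s_j <- circ_sites_on_junction(junction2, c(mirX = mir),
                                max_expectation = 0)
  s_l <- predict_sites(mir, substr(jseq2, 1, 100), max_expectation = 0)
  expect_equal(s_j$target_start, s_l$target_start)
  expect_false(any(s_j$junction_spanning))
})

test_that("stringent scanning of random sequence finds nothing", {
  set.seed(76)
  target <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  s <- predict_sites(mk_mirna(seed = 77), target, max_expectation = 0)
  expect_equal(nrow(s), 0)
})

test_that("the sponge network is tripartite, DE-constrained and pruned", {
  circ_sites <- data.frame(
    target = c("c1", "c1", "c2", "c3"),
    mirna = c("m1", "m2", "m1", "m3"),
    expectation = c(0, 1, 2, 0))
  gene_sites <- data.frame(
    target = c("g1", "g2", "g3", "g4"),
    mirna = c("m1", "m1", "m1", "m2"),
    expectation = c(0, 0.5, 1, 0))
  # c3 not DE; g4's miRNA m2 keeps both edge types via c1
  net <- build_network(c("c1", "c2"), c("g1", "g2", "g3", "g4"),
                       circ_sites, gene_sites)
  expect_equal(unname(net$counts["n_circ"]), 2L)
  expect_equal(unname(net$counts["n_mirna"]), 2L)
  expect_equal(unname(net$counts["n_mrna"]), 4L)
  # 3 circ-miRNA edges (c1-m1, c1-m2, c2-m1) + 4 miRNA-mRNA edges
  expect_equal(unname(net$counts["n_edges"]), 7L)
  expect_setequal(unique(net$edges$edge_type),
                  c("circ-miRNA", "miRNA-mRNA"))
  # no circ-mRNA edge can exist: sources of miRNA-mRNA edges are miRNAs
  ge <- net$edges[net$edges$edge_type == "miRNA-mRNA", ]
  expect_true(all(ge$source %in% c("m1", "m2")))

  # miRNA without mRNA edges is pruned
  net2 <- build_network(c("c3"), character(0), circ_sites, gene_sites)
  expect_equal(unname(net2$counts["n_edges"]), 0L)

  # no DE circRNA: empty network
  net3 <- build_network(character(0), c("g1"), circ_sites, gene_sites)
  expect_equal(unname(net3$counts["n_circ"]), 0L)
  expect_equal(unname(net3$counts["n_edges"]), 0L)
})

test_that("network export round-trips node and edge counts", {
  circ_sites <- data.frame(target = c("c1", "c2"), mirna = "m1",
                           expectation = 0)
  gene_sites <- data.frame(target = c("g1", "g2", "g3"), mirna = "m1",
                           expectation = 0)
  net <- build_network(c("c1", "c2"), c("g1", "g2", "g3"),
                       circ_sites, gene_sites)
  expect_equal(unname(net$counts["n_edges"]), 5L)
  ef <- withr::local_tempfile(fileext = ".tsv")
  nf <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, ef, nf)
  edges <- read.delim(ef)
  nodes <- read.delim(nf)
  expect_equal(nrow(edges), 5)
  expect_equal(nrow(nodes), 6)

  empty <- build_network(character(0), character(0), circ_sites[0, ],
                         gene_sites[0, ])
  export_network(empty, ef, nf)
  expect_equal(nrow(read.delim(ef)), 0)
})
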