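test_that("RPB is junction reads per billion clean reads", {
  expect_equal(rpb(2, 1e9), 2)
  expect_equal(rpb(5, 5e7), 100)
  expect_equal(rpb(0, 1e9), 0)
  expect_error(rpb(1, 0), "positive")

  # linear in reads, inversely proportional to library size
  set.seed(61)
  r <- runif(20, 1, 500); cl <- runif(20, 1e8, 2e9)
  expect_equal(rpb(3 * r, cl), 3 * rpb(r, cl))
  expect_equal(rpb(r, 2 * cl), rpb(r, cl) / 2)
})

test_that("expression bins close the gap at 500 RPB", {
  expect_equal(as.character(bin_expression(c(99.9, 100, 500, 500.5))),
               c("low", "medium", "medium", "high"))
  expect_error(bin_expression(-1), "non-negative")
  # monotone non-decreasing in RPB
  x <- sort(runif(100, 0, 1000))
  expect_true(!is.unsorted(bin_expression(x)))
})

test_that("FPKM follows its defining formula", {
  expect_equal(fpkm(10, 2000, 1e6), 5)
  expect_equal(fpkm(0, 2000, 1e6), 0)
  expect_equal(fpkm(10, 2000, 2e6), fpkm(10, 2000, 1e6) / 2)
  expect_error(fpkm(1, 0, 1e6), "positive")
})

de_fixture <- function(n, fold_vec, mu = 100, seed = 62, disp = 0.1) {
  set.seed(seed)
  mus <- matrix(mu, n, 6)
  mus[, 4:6] <- mu * fold_vec
  counts <- matrix(rnbinom(n * 6, mu = mus, size = 1 / disp), nrow = n,
                   dimnames = list(sprintf("f%04d", 1:n),
                                   c(paste0("CK_R", 1:3),
                                     paste0("C6_R", 1:3))))
  counts
}

test_that("equal counts give log2FC 0 and p 1", {
  counts <- matrix(50, 3, 6,
                   dimnames = list(c("a", "b", "c"),
                                   c(paste0("CK_R", 1:3),
                                     paste0("C6_R", 1:3))))
  ls <- setNames(rep(1e9, 6), colnames(counts))
  d <- de_test(counts, ls, paste0("C6_R", 1:3), paste0("CK_R", 1:3))
  expect_equal(d$log2fc, rep(0, 3))
  expect_equal(d$p, rep(1, 3))
  expect_equal(d$direction, rep("ns", 3))
})

test_that("p-values are invariant to global library rescaling", {
  counts <- de_fixture(100, 1)
  ls <- setNames(runif(6, 0.9e9, 1.1e9), colnames(counts))
  d1 <- de_test(counts, ls, paste0("C6_R", 1:3), paste0("CK_R", 1:3))
  d2 <- de_test(counts, ls * 7, paste0("C6_R", 1:3), paste0("CK_R", 1:3))
  expect_equal(d1$p, d2$p)
  expect_equal(d1$log2fc, d2$log2fc)
})

test_that("single-replicate groups fall back to the Poisson exact test", {
  counts <- de_fixture(20, 2)[, c(1, 4)]
  ls <- setNames(rep(1e9, 2), colnames(counts))
  expect_warning(
    d <- de_test(counts, ls, "C6_R1", "CK_R1"),
    "Poisson"
  )
  expect_true(all(d$p >= 0 & d$p <= 1))
  expect_error(de_test(counts, ls, "nope", "CK_R1"), "absent")
})

test_that("the exact NB test tracks the edgeR implementation", {
  skip_if_not_installed("edgeR")
  counts <- de_fixture(250, sample(c(1, 1, 1, 4, 0.25), 250, TRUE),
                       seed = 63)
  ls <- setNames(rep(1e9, 6), colnames(counts))
  mine <- de_test(counts, ls, paste0("C6_R", 1:3), paste0("CK_R", 1:3),
                  dispersion = 0.1)
  y <- edgeR::DGEList(counts = counts, group = rep(c("CK", "C6"), each = 3),
                      lib.size = rep(1e9, 6))
  y$common.dispersion <- 0.1
  ref <- edgeR::exactTest(y, pair = c("CK", "C6"))$table
  expect_gt(cor(mine$p, ref$PValue, method = "spearman"), 0.99)
  expect_gt(mean((mine$p <= 0.05) == (ref$PValue <= 0.05)), 0.97)
  expect_lt(max(abs(mine$log2fc - ref$logFC)), 0.2)
})

test_that("timecourse DE takes the per-feature best comparison", {
  set.seed(64)
  samples <- paste0(rep(c("CK", "C6", "C12"), each = 3), "_R", 1:3)
  mus <- matrix(100, 50, 9)
  mus[1:5, 4:6] <- 400    # responds at C6 only
  mus[6:10, 7:9] <- 400   # responds at C12 only
  counts <- matrix(rnbinom(450, mu = mus, size = 10), nrow = 50,
                   dimnames = list(sprintf("f%02d", 1:50), samples))
  ls <- setNames(rep(1e9, 9), samples)
  dec <- de_timecourse(counts, ls, c("C6", "C12"), "CK")
  up <- dec$combined$id[dec$combined$direction == "up"]
  expect_true(all(sprintf("f%02d", 1:10) %in% up))
  expect_true(all(grepl("C6", dec$combined$comparison[1:5])))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # N = 20, K = 5, n = 5, k = 4:
  # p = (C(5,4) C(15,1) + C(5,5) C(15,0)) / C(20,5) = 76/15504
  pop <- sprintf("g%02d", 1:20)
  study <- c("g01", "g02", "g03", "g04", "g06")
  tm <- data.frame(id = sprintf("g%02d", 1:5), term = "T1")
  res <- hypergeom_enrich(study, pop, tm)
  p_oracle <- (choose(5, 4) * choose(15, 1) +
                 choose(5, 5) * choose(15, 0)) / choose(20, 5)
  expect_equal(res$p, p_oracle)
  expect_equal(res$p, 76 / 15504)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 4L, K = 5L, n = 5L, N = 20L))

  # study = population makes every term's p exactly 1
  res2 <- hypergeom_enrich(pop, pop, tm)
  expect_equal(res2$p, 1)

  # term with no population members
  tm0 <- data.frame(id = "absent", term = "T0")
  expect_equal(hypergeom_enrich(study, pop, tm0)$p, numeric(0))
  expect_error(hypergeom_enrich(c(study, "zzz"), pop, tm), "subset")
})
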