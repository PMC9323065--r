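test_that("fpkm follows the count x 1e9 / (length x library) formula", {
  expect_equal(fpkm(matrix(100), lengths = 1000,
                    librarySizes = 1e6)[1, 1], 100)
  expect_equal(fpkm(matrix(0), lengths = 500,
                    librarySizes = 1e6)[1, 1], 0)
  expect_error(fpkm(matrix(1), lengths = 0, librarySizes = 1), "positive")

  # per-sample identity when library size is total counts
  set.seed(2)
  cn <- matrix(rpois(200, 50), nrow = 50)
  len <- sample(200:5000, 50)
  fk <- fpkm(cn, len)
  expect_equal(colSums(fk * len), rep(1e9, 4))
})

test_that("size factors match the DESeq median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  cn <- matrix(rnbinom(600 * 6, mu = 80, size = 10), ncol = 6)
  cn[, 4:6] <- cn[, 4:6] * 2L  # doubled depth
  expect_equal(sizeFactors(cn),
               unname(DESeq2::estimateSizeFactorsForMatrix(cn)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("log2 fold changes use pseudocount-1 shrunken means", {
  # a background of unchanged genes pins the size factors at 1, so the
  # gene of interest has normalized means exactly 10 and 40
  bg <- matrix(rep(c(20L, 35L, 50L, 80L), each = 6), ncol = 6,
               byrow = TRUE)
  cn <- rbind(hit = c(10L, 10L, 10L, 40L, 40L, 40L), bg)
  rownames(cn) <- c("hit", paste0("bg", 1:4))
  tab <- deTest(cn, rep(c("control", "salt"), each = 3))
  expect_equal(tab$log2fc[tab$gene == "hit"], log2(41 / 11))
  expect_equal(tab$log2fc[tab$gene != "hit"], rep(0, 4))

  # identical data in both groups: zero fold change everywhere
  set.seed(8)
  half <- matrix(rnbinom(300, mu = 50, size = 20), ncol = 3)
  tab0 <- deTest(cbind(half, half), rep(c("a", "b"), each = 3),
                 contrast = c("b", "a"))
  expect_true(all(tab0$log2fc == 0))
  expect_true(all(tab0$pvalue >= 0.999))
})

test_that("swapping condition labels negates fold changes only", {
  se <- simulateCounts(tinyConfig(seed = 13, nGenes = 400L))
  cn <- SummarizedExperiment::assay(se)
  fwd <- deTest(cn, se$condition, contrast = c("salt", "control"))
  rev <- deTest(cn, se$condition, contrast = c("control", "salt"))
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$pvalue, rev$pvalue)
})

test_that("all-zero genes are reported non-significant", {
  cn <- rbind(zero = rep(0L, 6),
              expr = c(10L, 12L, 9L, 50L, 47L, 55L))
  cn <- rbind(cn, matrix(rpois(60 * 6, 30), ncol = 6,
                         dimnames = list(paste0("f", 1:60), NULL)))
  tab <- deTest(cn, rep(c("control", "salt"), each = 3))
  expect_equal(tab$pvalue[tab$gene == "zero"], 1)
  expect_equal(tab$log2fc[tab$gene == "zero"], 0)
})

test_that("DEG calls apply strict fold-change and p filters", {
  tab <- data.frame(
    gene = paste0("g", 1:5),
    log2fc = c(2, -2, 0.5, 3, -1.2),
    pvalue = c(1e-4, 1e-4, 1e-4, 0.5, 1e-4),
    padj = c(1e-3, 1e-3, 1e-3, 0.6, 1e-3))
  called <- callDegs(tab)
  expect_equal(unname(attr(called, "summary")[c("n_up", "n_down")]),
               c(1L, 2L))
  expect_equal(called$call, c("up", "down", "ns", "ns", "down"))

  # boundary: |lfc| exactly 1 is not a DEG even at tiny p
  edge <- data.frame(gene = "e", log2fc = 1.0, pvalue = 1e-3,
                     padj = 1e-3)
  expect_equal(callDegs(edge)$call, "ns")

  s <- degSummary(called)
  expect_equal(unname(s["n_deg"]), unname(s["n_up"] + s["n_down"]))
})

test_that("common DEGs intersect the up-or-down calls symmetrically", {
  a <- data.frame(gene = c("g1", "g2", "g3"),
                  call = c("up", "down", "ns"))
  b <- data.frame(gene = c("g1", "g2", "g3"),
                  call = c("down", "ns", "up"))
  expect_equal(commonDegs(a, b), "g1")
  expect_equal(commonDegs(b, a), commonDegs(a, b))
  expect_equal(commonDegs(a, a), c("g1", "g2"))
  ns <- transform(a, call = "ns")
  expect_length(commonDegs(a, ns), 0)
})

test_that("planted effects are recovered and the null is calibrated", {
  recovery <- vapply(1:10, function(s) {
    cfg <- simConfig(seed = s, nGenes = 1500L, degFraction = 0.05,
                     lfcEffect = 4, nbDispersion = 0.05)
    se <- simulateCounts(cfg)
    calls <- callDegs(deTest(se))
    truth <- SummarizedExperiment::rowData(se)$direction
    mean(calls$call[truth != "ns"] != "ns")
  }, numeric(1))
  expect_gte(mean(recovery), 0.90)

  typeI <- vapply(1:10, function(s) {
    cfg <- simConfig(seed = 100 + s, nGenes = 1500L, degFraction = 0)
    tab <- deTest(simulateCounts(cfg))
    mean(tab$pvalue < 0.01)
  }, numeric(1))
  expect_gte(mean(typeI), 0.001)
  expect_lte(mean(typeI), 0.03)
  # full calls under the null: at most 3% of genes
  cfg <- simConfig(seed = 77, nGenes = 2000L, degFraction = 0)
  calls <- callDegs(deTest(simulateCounts(cfg)))
  expect_lte(mean(calls$call != "ns"), 0.03)
})

test_that("p-values on label-permuted data are approximately uniform", {
  cfg <- simConfig(seed = 7, nGenes = 4000L, degFraction = 0)
  se <- simulateCounts(cfg)
  cn <- SummarizedExperiment::assay(se)
  set.seed(7)
  perm <- sample(colnames(cn))
  tab <- deTest(cn[, perm], se$condition)
  # counts below ~10 are too discrete for the normal reference to give
  # continuous p-values; uniformity is asserted where the test is meant
  # to operate
  keep <- (tab$baseMeanRef + tab$baseMeanTreat) / 2 >= 10
  ks <- suppressWarnings(stats::ks.test(tab$pvalue[keep], "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("contrasts sharing planted DEGs yield a matching overlap", {
  cfg <- simConfig(seed = 41, nGenes = 1000L, degFraction = 0.05,
                   lfcEffect = 4, nbDispersion = 0.02)
  seA <- simulateCounts(cfg, stream = "A")
  seB <- simulateCounts(cfg, stream = "B")
  # same config plants the same fraction; independent streams pick
  # different gene subsets, so build the truth overlap explicitly
  truthA <- rownames(seA)[SummarizedExperiment::rowData(seA)$planted]
  truthB <- rownames(seB)[SummarizedExperiment::rowData(seB)$planted]
  shared <- intersect(truthA, truthB)
  common <- commonDegs(callDegs(deTest(seA)), callDegs(deTest(seB)))
  # nearly all genes planted in both contrasts are recovered in both
  expect_gte(length(intersect(common, shared)),
             0.8 * length(shared))
})
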