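test_that("config validation rejects impossible designs", {
  expect_error(simConfig(censusDays = c(4, 2, 6)), "increasing")
  expect_error(simConfig(tolerantFraction = 1.3), "proportion")
  expect_error(simConfig(nSeedsPerDish = 0), ">= 1")
  expect_error(simConfig(saltLevels = c(0.13, -1)), "positive")
})

test_that("germination simulation is seeded, monotone and bounded", {
  cfg <- tinyConfig(seed = 11)
  a <- simulateGermination(cfg)
  b <- simulateGermination(cfg)
  expect_identical(a, b)
  expect_false(identical(a, simulateGermination(tinyConfig(seed = 12))))

  cs <- a$census
  expect_true(all(cs$germinated >= 0 & cs$germinated <= cs$sown))
  byDish <- split(cs, cs[c("accession", "condition", "replicate")],
                  drop = TRUE)
  for (d in byDish) {
    d <- d[order(d$day), ]
    expect_false(is.unsorted(d$germinated))
  }
  # lengths recorded only at the final census, non-negative
  final <- cs$day == max(cfg@censusDays)
  expect_true(all(is.na(cs$plumule_length[!final])))
  expect_true(all(cs$plumule_length[final] >= 0))
})

test_that("zero salt asymptote gives zero germination under salt", {
  sim <- simulateGermination(tinyConfig(seed = 2), saltAsymptote = 0)
  salt <- sim$census[sim$census$condition == "salt", ]
  expect_true(all(salt$germinated == 0))
  ctl <- sim$census[sim$census$condition == "control", ]
  expect_gt(sum(ctl$germinated), 0)
})

test_that("latent tolerant accessions rise to the top of the screen", {
  cfg <- simConfig(seed = 1, nAccessions = 104L, tolerantFraction = 0.2)
  sim <- simulateGermination(cfg)
  rel <- relativeGerminationTraits(germinationTraits(sim$census))
  st <- fuzzyEvaluate(relativeToLong(rel))
  topHalf <- st$accession[st$total_rank <= nrow(st) / 2]
  tolerant <- names(sim$classes)[sim$classes == "tolerant"]
  expect_gte(mean(tolerant %in% topHalf), 0.8)
})

test_that("seedling simulation responds to class and null effects", {
  cls <- c(FM001 = "tolerant", FM002 = "sensitive")
  cfg <- tinyConfig(seed = 3)
  tab <- simulateSeedling(cfg, cls)
  expect_identical(tab, simulateSeedling(cfg, cls))
  expect_true(all(tab$biomass > 0 & tab$height_initial > 0 &
                  tab$A663 >= 0 & tab$Na >= 0))

  # null effect: all relative traits concentrate near 1
  null <- simulateSeedling(cfg, cls,
                           saltEffect = c(tolerant = 0, sensitive = 0))
  rel <- relativeSeedlingTraits(null)
  expect_true(all(abs(rel$value - 1) < 0.25))
  expect_lt(abs(median(rel$value) - 1), 0.05)

  # strong separation: every tolerant accession outranks every sensitive
  cls18 <- setNames(rep(c("tolerant", "sensitive"), c(5, 13)),
                    sprintf("FM%03d", 1:18))
  tab18 <- simulateSeedling(simConfig(seed = 5), cls18,
                            saltEffect = c(tolerant = 0.15,
                                           sensitive = 0.85))
  st <- fuzzyEvaluate(relativeSeedlingTraits(tab18))
  rk <- setNames(st$total_rank, st$accession)
  expect_lt(max(rk[names(cls18)[cls18 == "tolerant"]]),
            min(rk[names(cls18)[cls18 == "sensitive"]]))
})

test_that("count simulation has the declared NB structure", {
  cfg <- tinyConfig(seed = 4, nGenes = 500L)
  se <- simulateCounts(cfg)
  expect_identical(SummarizedExperiment::assay(se),
                   SummarizedExperiment::assay(simulateCounts(cfg)))
  expect_true(all(SummarizedExperiment::assay(se) >= 0))
  rd <- SummarizedExperiment::rowData(se)
  expect_true(all(rd$length >= 200 & rd$length <= 10000))
  expect_equal(sum(rd$planted), floor(500 * cfg@degFraction))

  # no planted effects
  se0 <- simulateCounts(tinyConfig(seed = 4, degFraction = 0))
  expect_true(all(SummarizedExperiment::rowData(se0)$direction == "ns"))

  # moment check: empirical means within 3 SE of an equal baseline
  n <- 2L * cfg@nSamplesPerGroup
  alpha <- 0.05
  mu <- 100
  cfgFlat <- simConfig(seed = 9, nGenes = 2000L, degFraction = 0,
                       nbDispersion = alpha)
  seF <- simulateCounts(cfgFlat)
  cn <- SummarizedExperiment::assay(seF)
  # rescale each gene's true mean to a common value is not possible
  # post-hoc, so check the relationship mean/var instead: regress the
  # per-gene variance on mu + alpha mu^2
  m <- rowMeans(cn); v <- apply(cn, 1, var)
  keep <- m > 20
  alphaHat <- median((v[keep] - m[keep]) / m[keep]^2)
  expect_lt(abs(alphaHat - alpha), 0.05)
})

test_that("annotation simulation respects sizes and determinism", {
  cfg <- tinyConfig(seed = 6, genesPerTerm = c(5L, 5L), nTerms = 40L)
  genes <- sprintf("G%05d", 1:200)
  ann <- simulateAnnotations(cfg, genes)
  expect_identical(ann, simulateAnnotations(cfg, genes))
  expect_true(all(lengths(ann$terms) == 5L))
  expect_length(ann$terms, 40L)
  expect_true(all(unlist(ann$terms) %in% genes))
  expect_true(all(table(ann$tf$gene) == 1L))  # one family per gene
})

test_that("ppi simulation plants recoverable cliques", {
  cfg <- tinyConfig(seed = 7, backgroundEdgeProb = 0)
  genes <- sprintf("G%05d", 1:100)
  ppi <- simulatePPI(cfg, genes)
  expect_identical(ppi, simulatePPI(cfg, genes))
  g <- buildGraph(ppi$edges, threshold = 0.9)
  found <- Filter(function(x) length(x) >= 2, maximalCliques(g))
  expect_setequal(
    vapply(found, paste, character(1), collapse = ","),
    vapply(ppi$cliques, paste, character(1), collapse = ","))

  withBg <- simulatePPI(tinyConfig(seed = 7, backgroundEdgeProb = 0.05),
                        genes)
  expect_true(any(withBg$edges$confidence < 0.9))
  expect_true(all(withBg$edges$confidence >= 0 &
                  withBg$edges$confidence <= 1))
})

test_that("writeSimulation emits a complete, re-readable bundle", {
  dir <- withr::local_tempdir()
  cfg <- tinyConfig(seed = 8)
  paths <- writeSimulation(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  census <- readTsv(paths$census)
  expect_identical(nrow(census), nrow(simulateGermination(cfg)$census))
  terms <- readGmt(paths$terms)
  expect_length(terms, cfg@nTerms)
  se <- readCounts(paths$counts_sensitive, paths$lengths_sensitive,
                   paths$samples_sensitive)
  expect_identical(
    unname(SummarizedExperiment::assay(se)),
    unname(SummarizedExperiment::assay(
      simulateCounts(cfg, stream = "sensitive"))))
})
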