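test_that("graph building thresholds, rescales and cleans the edges", {
  edges <- data.frame(geneA = c("a", "b", "c", "d", "d"),
                      geneB = c("b", "c", "a", "e", "d"),
                      confidence = c(0.95, 0.5, 0.91, 0.99, 0.97))
  expect_warning(g <- buildGraph(edges), "self-loop")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d", "e"))
  got <- igraph::as_data_frame(g)
  expect_equal(nrow(got), 3L)  # b-c below threshold, d-d dropped
  expect_true(all(got$confidence >= 0.9))

  # all below threshold: empty edge set, vertices retained
  g0 <- buildGraph(data.frame(geneA = "a", geneB = "b",
                              confidence = 0.5))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 2)

  # 0-1000 STRING dialect: auto-rescaled
  gs <- buildGraph(data.frame(geneA = c("a", "a"), geneB = c("b", "c"),
                              confidence = c(950, 400)))
  expect_equal(igraph::ecount(gs), 1)
  expect_equal(igraph::E(gs)$confidence, 0.95)

  # duplicate pair keeps the max confidence
  gd <- buildGraph(data.frame(geneA = c("a", "b"), geneB = c("b", "a"),
                              confidence = c(0.92, 0.99)))
  expect_equal(igraph::E(gd)$confidence, 0.99)

  expect_error(buildGraph(data.frame(geneA = "a", geneB = "b",
                                     confidence = NA)), "malformed")
  expect_error(buildGraph(data.frame(x = 1)), "columns")
})

test_that("edge count is preserved above the threshold", {
  set.seed(9)
  n <- 80
  pairs <- t(combn(sprintf("p%03d", 1:n), 2))
  idx <- sample(nrow(pairs), 2232)
  edges <- data.frame(geneA = pairs[idx, 1], geneB = pairs[idx, 2],
                      confidence = runif(2232, 0.9, 1))
  g <- buildGraph(edges, threshold = 0.9)
  expect_equal(igraph::ecount(g), 2232)
})

test_that("maximal cliques are found and ordered deterministically", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(maximalCliques(k4), list(letters[1:4]))

  path <- igraph::make_graph(~ a - b, b - c)
  expect_equal(maximalCliques(path), list(c("a", "b"), c("b", "c")))
})

test_that("clique enumeration agrees with brute force on random graphs", {
  set.seed(23)
  for (i in 1:25) {
    g <- randomGraph(sample(5:10, 1), runif(1, 0.2, 0.7))
    expect_identical(maximalCliques(g), bruteMaximalCliques(g))
  }
})

test_that("MCC scores match their clique-sum definition", {
  # 5-clique with a pendant high-confidence edge on one member
  members <- paste0("c", 1:5)
  pr <- t(combn(members, 2))
  edges <- data.frame(geneA = c(pr[, 1], "c1"),
                      geneB = c(pr[, 2], "x"),
                      confidence = 0.95)
  g <- buildGraph(edges)
  sc <- mccScores(g)
  mcc <- setNames(sc$mcc, sc$gene)
  expect_equal(unname(mcc["c1"]), 25)             # 4! + 1!
  expect_equal(unname(mcc[paste0("c", 2:5)]), rep(24, 4))
  expect_equal(unname(mcc["x"]), 1)
  expect_equal(sc$rank[sc$gene == "c1"], 1L)

  # isolated node scores zero
  gi <- buildGraph(data.frame(geneA = "a", geneB = "b",
                              confidence = 0.95), nodes = c("a", "b", "z"))
  sci <- mccScores(gi)
  expect_equal(sci$mcc[sci$gene == "z"], 0)
  # node in a single triangle scores 2! = 2
  tri <- buildGraph(data.frame(geneA = c("a", "b", "c"),
                               geneB = c("b", "c", "a"),
                               confidence = 0.95))
  expect_equal(mccScores(tri)$mcc, rep(2, 3))
})

test_that("MCC equals brute force on random seeded graphs", {
  set.seed(29)
  for (i in 1:40) {
    g <- randomGraph(sample(6:12, 1), runif(1, 0.15, 0.6))
    sc <- mccScores(g)
    expect_equal(setNames(sc$mcc, sc$gene)[order(sc$gene)],
                 bruteMcc(g))
  }
})

test_that("MCC is equivariant under node relabeling", {
  set.seed(31)
  g <- randomGraph(10, 0.4)
  perm <- sample(igraph::V(g)$name)
  g2 <- g
  names(perm) <- igraph::V(g)$name
  igraph::V(g2)$name <- unname(perm[igraph::V(g)$name])
  sc1 <- mccScores(g); sc2 <- mccScores(g2)
  m1 <- setNames(sc1$mcc, unname(perm[sc1$gene]))
  m2 <- setNames(sc2$mcc, sc2$gene)
  expect_equal(m1[order(names(m1))], m2[order(names(m2))])
})

test_that("deleting an isolated node leaves other scores unchanged", {
  set.seed(33)
  g <- randomGraph(8, 0.4)
  g2 <- igraph::add_vertices(g, 1, name = "zz")
  sc <- mccScores(g); sc2 <- mccScores(g2)
  expect_equal(setNames(sc$mcc, sc$gene),
               setNames(sc2$mcc, sc2$gene)[sc$gene])
})

test_that("top hubs break factorial ties lexicographically", {
  # one 11-clique: every member scores 10!
  members <- sprintf("m%02d", 1:11)
  pr <- t(combn(members, 2))
  g <- buildGraph(data.frame(geneA = pr[, 1], geneB = pr[, 2],
                             confidence = 0.95))
  sc <- mccScores(g)
  expect_true(all(sc$mcc == factorial(10)))
  th <- topHubs(sc, g, k = 10)
  expect_equal(th$hubs$gene, sort(members)[1:10])

  expect_warning(all11 <- topHubs(sc, g, k = 12), "exceeds")
  expect_equal(nrow(all11$hubs), 11L)

  # planted-clique simulation: hubs come from the planted cliques
  cfg <- tinyConfig(seed = 19, backgroundEdgeProb = 0.01)
  ppi <- simulatePPI(cfg, sprintf("G%05d", 1:100))
  gg <- buildGraph(ppi$edges)
  scg <- mccScores(gg)
  hub <- topHubs(scg, gg, k = 6)$hubs
  expect_true(all(hub$gene %in% unlist(ppi$cliques)))
})
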