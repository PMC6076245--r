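test_that("relations parsing orients RB/RN rows, deduplicates and skips", {
  tf <- withr::local_tempfile()
  writeLines(c("A\tRB\tB", "B\tRN\tA", "A\tSY\tC"), tf)
  edges <- suppressMessages(readRelations(tf))
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$parent, "B")
  expect_equal(edges$child, "A")
  expect_equal(attr(edges, "skipped"), 1L)

  # reversed orientation convention flips the parent
  rev <- suppressMessages(readRelations(tf, rbSecondBroader = FALSE))
  expect_equal(rev$parent, "A")
  expect_equal(rev$child, "B")

  # header row tolerated, self-relations dropped
  tf2 <- withr::local_tempfile()
  writeLines(c("CUI1\tREL\tCUI2", "X\tRB\tY", "Z\tRB\tZ"), tf2)
  edges2 <- readRelations(tf2)
  expect_equal(nrow(edges2), 1L)

  tf3 <- withr::local_tempfile()
  writeLines("A\tSY\tB", tf3)
  expect_error(suppressMessages(readRelations(tf3)), "no usable")
  tf4 <- withr::local_tempfile()
  writeLines("A\tRB", tf4)
  expect_error(readRelations(tf4), "3 tab-separated")
})

test_that("network construction roots, breaks cycles, adds virtual root", {
  net <- buildNetwork(data.frame(parent = c("R", "A"), child = c("A", "B")))
  expect_equal(rootConcept(net), "R")
  expect_setequal(concepts(net), c("R", "A", "B"))

  cyc <- buildNetwork(data.frame(parent = c("R", "A", "B"),
                                 child = c("A", "B", "A")))
  expect_equal(nrow(hierarchyEdges(cyc)), 2L)
  expect_equal(rootConcept(cyc), "R")

  multi <- buildNetwork(data.frame(parent = c("R1", "R2"),
                                   child = c("A", "B")))
  expect_equal(rootConcept(multi), "VROOT")
  expect_setequal(multi@childIndex[["VROOT"]], c("R1", "R2"))
})

test_that("any input edge list yields an acyclic rooted network", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    ids <- sprintf("N%02d", seq_len(n))
    e <- unique(data.frame(
      parent = sample(ids, 3 * n, replace = TRUE),
      child = sample(ids, 3 * n, replace = TRUE)))
    e <- e[e$parent != e$child, ]
    if (nrow(e) == 0) next
    net <- suppressMessages(buildNetwork(e))
    g <- igraph::graph_from_data_frame(
      hierarchyEdges(net)[, c("parent", "child")])
    expect_true(igraph::is_dag(g))
    # every concept reachable from the root
    expect_false(anyNA(net@depths))
  }
})

test_that("depth follows the shortest root path, root at depth 1", {
  net <- buildNetwork(data.frame(parent = c("R", "A"), child = c("A", "B")))
  expect_equal(conceptDepth(net, "R"), 1L)
  expect_equal(conceptDepth(net, "B"), 3L)
  diamond <- buildNetwork(data.frame(
    parent = c("R", "R", "A", "B"), child = c("A", "B", "C", "C")))
  expect_equal(conceptDepth(diamond, "C"), 3L)
  expect_error(conceptDepth(net, "nope"), "unknown concept")
})

test_that("lowest common subsumer is deepest, ties lexicographic", {
  sib <- buildNetwork(data.frame(parent = c("R", "A", "A"),
                                 child = c("A", "B", "C")))
  expect_equal(lowestCommonSubsumer(sib, "B", "C"), "A")
  expect_equal(lowestCommonSubsumer(sib, "B", "B"), "B")
  # two equally deep common ancestors X1, X2 -> lexicographically first
  tie <- buildNetwork(data.frame(
    parent = c("R", "R", "X1", "X2", "X1", "X2"),
    child = c("X1", "X2", "U", "U", "V", "V")))
  expect_equal(lowestCommonSubsumer(tie, "U", "V"), "X1")
})

test_that("Wu-Palmer similarity matches hand-evaluated cases", {
  chain <- buildNetwork(data.frame(parent = c("R", "A"), child = c("A", "B")))
  expect_equal(wupSimilarity(chain, "B", "B"), 1)
  expect_equal(wupSimilarity(chain, "A", "B"), 0.8)
  expect_equal(wupSimilarity(chain, "R", "A"), 2 / 3)
  sib <- buildNetwork(data.frame(parent = c("R", "A", "A"),
                                 child = c("A", "B", "C")))
  expect_equal(wupSimilarity(sib, "B", "C"), 2 / 3)
})

test_that("similarity is symmetric, in (0,1], 1 only on identity", {
  edges <- randomDagEdges(50, seed = 7)
  net <- buildNetwork(edges)
  ids <- concepts(net)
  set.seed(7)
  pairs <- cbind(sample(ids, 60, replace = TRUE),
                 sample(ids, 60, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    s <- wupSimilarity(net, pairs[i, 1], pairs[i, 2])
    expect_gt(s, 0)
    expect_lte(s, 1)
    expect_equal(s, wupSimilarity(net, pairs[i, 2], pairs[i, 1]))
    if (pairs[i, 1] != pairs[i, 2]) expect_lt(s, 1)
  }
})

test_that("depth, lcs and similarity agree with igraph enumeration", {
  for (seed in c(3, 4)) {
    edges <- randomDagEdges(40, seed = seed)
    net <- buildNetwork(edges)
    root <- rootConcept(net)
    od <- oracleDepths(edges, root)
    expect_equal(unname(conceptDepth(net, names(od))), unname(od),
                 ignore_attr = TRUE)
    ids <- concepts(net)
    set.seed(seed)
    pairs <- cbind(sample(ids, 30, replace = TRUE),
                   sample(ids, 30, replace = TRUE))
    for (i in seq_len(nrow(pairs))) {
      c1 <- pairs[i, 1]; c2 <- pairs[i, 2]
      expect_equal(lowestCommonSubsumer(net, c1, c2),
                   oracleLcs(edges, root, c1, c2))
      expect_equal(wupSimilarity(net, c1, c2),
                   oracleWup(edges, root, c1, c2))
    }
  }
})

test_that("parent-child edge weights increase strictly with depth", {
  n <- 11
  ids <- sprintf("L%02d", seq_len(n))
  chain <- weightEdges(buildNetwork(
    data.frame(parent = ids[-n], child = ids[-1])))
  w <- hierarchyEdges(chain)$weight
  d <- seq_len(n - 1)                     # parent depths along the chain
  expect_equal(w, 2 * d / (1 + 2 * d))
  expect_true(all(diff(w) > 0))
})

test_that("network edge-list serialization round-trips", {
  net <- weightEdges(buildNetwork(randomDagEdges(15, seed = 2)))
  tf <- withr::local_tempfile()
  writeNetwork(net, tf)
  back <- readNetwork(tf)
  expect_equal(hierarchyEdges(back), hierarchyEdges(net))
  expect_equal(rootConcept(back), rootConcept(net))
})
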