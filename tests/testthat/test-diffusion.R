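test_that("column normalization yields stochastic columns and self-loops", {
  # two concepts, one edge: single-entry columns normalize to 1
  net <- weightEdges(buildNetwork(data.frame(parent = "A", child = "B")))
  W <- transitionMatrix(net)
  expect_equal(as.matrix(W), matrix(c(0, 1, 1, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B"))))
  # star: column of the center splits proportionally to edge weights
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "x"), c("a", "b", "x")))
  A["a", "x"] <- A["x", "a"] <- 0.6
  A["b", "x"] <- A["x", "b"] <- 0.9
  net2 <- buildNetwork(data.frame(parent = c("x", "x"), child = c("a", "b")))
  net2@edges$weight <- c(0.6, 0.9)
  W2 <- as.matrix(transitionMatrix(net2))
  expect_equal(W2[c("a", "b"), "x"], c(a = 0.4, b = 0.6))
  expect_equal(unname(Matrix::colSums(W2)), rep(1, 3))
})

test_that("seed vectors spread uniform mass over mapped annotations", {
  net <- buildNetwork(data.frame(parent = c("R", "R"), child = c("A", "B")))
  p0 <- makeSeed(c("A", "B"), net)
  expect_equal(p0[["A"]], 0.5)
  expect_equal(sum(p0), 1)
  p1 <- suppressMessages(makeSeed(c("A", "B", "ZZZ"), net))
  expect_equal(p1[["A"]], 0.5)
  expect_message(makeSeed(c("A", "ZZZ"), net), "skipped")
  expect_error(suppressMessages(makeSeed("ZZZ", net)), "maps into")
})

test_that("RWR reaches the two-node fixed point and conserves mass", {
  W <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("u", "v"), c("u", "v")))
  p0 <- c(u = 1, v = 0)
  p <- rwr(W, p0, r = 0.7)
  expect_equal(unname(p), c(10 / 13, 3 / 13), tolerance = 1e-7)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(rwrClosedForm(W, p0, r = 0.7)),
               c(10 / 13, 3 / 13), tolerance = 1e-12)
  # single concept: steady state is the seed for any r
  W1 <- matrix(1, 1, 1, dimnames = list("z", "z"))
  expect_equal(rwr(W1, c(z = 1), r = 0.3), c(z = 1))
  # r -> 1 limit: restart dominates
  expect_equal(unname(rwrClosedForm(W, p0, r = 0.999)), c(1, 0),
               tolerance = 1e-2)
  # contract violation
  expect_error(rwr(matrix(c(0.5, 0.2, 0.1, 0.3), 2), p0), "stochastic")
})

test_that("iterative and closed-form RWR agree on random networks", {
  for (seed in 1:5) {
    net <- randomWeightedNetwork(30, seed)
    W <- transitionMatrix(net)
    set.seed(seed)
    seeds <- sample(concepts(net), 3)
    p0 <- makeSeed(seeds, net)
    pi <- rwr(W, p0, r = 0.7, tol = 1e-10)
    pc <- rwrClosedForm(W, p0, r = 0.7)
    expect_lt(max(abs(pi - pc)), 1e-6)
    expect_equal(sum(pi), 1, tolerance = 1e-9)
    # restart floor: a seed keeps at least r * p0(seed)
    expect_true(all(pi[seeds] >= 0.7 * p0[seeds] - 1e-12))
  }
})

test_that("raising the restart probability pulls the walk toward the seed", {
  net <- randomWeightedNetwork(25, seed = 9)
  W <- transitionMatrix(net)
  p0 <- makeSeed(concepts(net)[c(3, 8)], net)
  dist <- vapply(c(0.2, 0.5, 0.7, 0.9), function(r)
    sum(abs(rwrClosedForm(W, p0, r = r) - p0)), numeric(1))
  expect_true(all(diff(dist) < 0))
})

test_that("universe projection preserves values without renormalizing", {
  net <- randomWeightedNetwork(10, seed = 4)
  W <- transitionMatrix(net)
  p0 <- makeSeed(concepts(net)[1], net)
  p <- rwrClosedForm(W, p0)
  expect_equal(unname(plantVector(p, concepts(net))), unname(p[concepts(net)]))
  sub <- concepts(net)[c(2, 5)]
  proj <- plantVector(p, sub)
  expect_equal(proj, p[sub])
  expect_true(all(proj <= p[sub] + 1e-15))
  expect_error(plantVector(p, c(sub, "missing")), "absent")
})

test_that("phenotype matrix stacks per-plant steady states, dense = sparse", {
  net <- randomWeightedNetwork(30, seed = 6)
  universe <- setdiff(concepts(net), rootConcept(net))
  set.seed(6)
  profiles <- list(p1 = sample(universe, 3), p2 = sample(universe, 2),
                   p3 = "not-a-concept")
  X <- suppressMessages(
    phenotypeVectors(net, profiles, universe))
  expect_equal(rownames(X), c("p1", "p2"))   # unmappable plant excluded
  expect_equal(colnames(X), universe)
  Xi <- suppressMessages(
    phenotypeVectors(net, profiles, universe, denseLimit = 0L))
  expect_equal(Xi, X, tolerance = 1e-7)
  # rows are projections of probability vectors
  expect_true(all(X >= 0) && all(rowSums(X) <= 1 + 1e-9))
})

test_that("ablation vectors are the bare annotation indicators", {
  universe <- c("A", "B", "C", "D")
  profiles <- list(p1 = c("A", "C"), p2 = c("B", "Z"), p3 = "Z")
  X <- suppressMessages(ablationVectors(profiles, universe))
  expect_equal(rownames(X), c("p1", "p2"))
  expect_equal(unname(X["p1", ]), c(1, 0, 1, 0))
  expect_equal(unname(X["p2", ]), c(0, 1, 0, 0))  # off-universe ignored
  # diffusion only adds mass: ablation support is inside RWR support
  net <- weightEdges(buildNetwork(data.frame(
    parent = c("R", "R", "A"), child = c("A", "B", "C"))))
  uni <- c("A", "B", "C")
  prof <- list(q = c("A", "C"))
  rwrX <- phenotypeVectors(net, prof, uni)
  ablX <- ablationVectors(prof, uni)
  expect_true(all(rwrX[1, ablX[1, ] > 0] > 0))
})
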