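test_that("cosine distance matches hand computations and rejects zeros", {
  expect_equal(cosineDistance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineDistance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2))
  expect_error(cosineDistance(c(0, 0), c(1, 0)), "zero vector")
})

test_that("dendrogram merges reflect the cosine distance structure", {
  X <- rbind(a = c(1, 0, 0, 0), b = c(1, 0, 0, 0.01), c = c(0, 0, 1, 0))
  hc <- plantDendrogram(X)
  m <- HerbPhenoNet:::.mergeMembers(hc$merge)
  expect_equal(m[[1]], c(1, 2))           # near-identical pair first
  expect_lt(hc$height[1], 1e-3)

  # two tight pairs merge before anything crosses
  Y <- rbind(p1 = c(1, 0.02, 0, 0), p2 = c(1, 0, 0.02, 0),
             p3 = c(0, 0.02, 0, 1), p4 = c(0, 0, 0.02, 1))
  hcY <- plantDendrogram(Y)
  mm <- lapply(HerbPhenoNet:::.mergeMembers(hcY$merge),
               function(ix) sort(rownames(Y)[ix]))
  expect_true(any(vapply(mm[1:2], identical, logical(1), c("p1", "p2"))))
  expect_true(any(vapply(mm[1:2], identical, logical(1), c("p3", "p4"))))

  # permuting rows leaves the member sets unchanged
  perm <- c(3, 1, 4, 2)
  mmPerm <- lapply(HerbPhenoNet:::.mergeMembers(
    plantDendrogram(Y[perm, ])$merge),
    function(ix) sort(rownames(Y)[perm][ix]))
  expect_setequal(mmPerm, mm)
})

test_that("bootstrap support is near 1 for a duplicated pair, with AU", {
  set.seed(42)
  X <- rbind(matrix(runif(8 * 30), 8, 30),
             dup1 = rep(c(5, 0), 15), dup2 = rep(c(5, 0), 15))
  rownames(X) <- c(paste0("n", 1:8), "dup1", "dup2")
  sup <- multiscaleBootstrap(X, nBoot = 100, seed = 9)
  i <- which(vapply(nodeMembers(sup), identical, logical(1),
                    c("dup1", "dup2")))
  expect_length(i, 1L)
  expect_true(all(bpValues(sup)[i, ] > 0.95))
  expect_gte(auValues(sup)[i], 0.95)
})

test_that("scales producing fewer than two columns are skipped", {
  X <- matrix(runif(12), 4, 3, dimnames = list(paste0("r", 1:4), NULL))
  expect_message(
    sup <- multiscaleBootstrap(X, nBoot = 20, seed = 1,
                               scales = c(0.34, 0.7, 1, 1.3)),
    "skipped scale")
  expect_equal(ncol(bpValues(sup)), 3L)
})

test_that("AU fit reproduces its closed forms", {
  scales <- seq(0.5, 1.4, by = 0.1)
  # bp = 0.5 at every scale: v = c = 0, AU = 0.5 exactly
  f <- auFit(rep(0.5, 10), scales, nBoot = 1000)
  expect_equal(f$au, 0.5)
  expect_equal(f$v, 0, tolerance = 1e-12)
  expect_equal(f$c, 0, tolerance = 1e-12)
  # curves stuck at a clamp bound take that bound's limit
  up <- auFit(rep(1, 10), scales, nBoot = 1000)
  expect_equal(up$au, 1000 / 1001)
  expect_equal(up$flag, "upper")
  dn <- auFit(rep(0, 10), scales, nBoot = 1000)
  expect_equal(dn$au, 1 / 1001)
  expect_equal(dn$flag, "lower")
  # bp curve generated from the model itself: the fit recovers (v, c)
  # exactly, and positive curvature c raises AU above bp at scale 1
  v <- -1; cc <- 0.3
  bp <- pnorm(-(v * sqrt(scales) + cc / sqrt(scales)))
  f2 <- auFit(bp, scales, nBoot = 1000)
  expect_equal(f2$v, v, tolerance = 1e-6)
  expect_equal(f2$c, cc, tolerance = 1e-6)
  expect_equal(f2$au, 1 - pnorm(v - cc), tolerance = 1e-6)
  expect_gte(f2$au, bp[scales == 1])
})

test_that("cluster selection keeps maximal supported nodes, never the root", {
  X <- rbind(a = c(1, 0, 0.01, 0), b = c(1, 0, 0, 0.01),
             c = c(0.01, 1, 0, 0), d = c(0, 1, 0.01, 0),
             e = c(0, 0.01, 1, 1))
  hc <- plantDendrogram(X)
  members <- lapply(HerbPhenoNet:::.mergeMembers(hc$merge),
                    function(ix) sort(rownames(X)[ix]))
  mk <- function(au) new("ClusterSupport",
    bp = matrix(au, nrow = length(au), ncol = 2),
    scales = c(0.5, 1), nBoot = 100L, au = au,
    fitError = rep(0, length(au)), flags = rep("", length(au)),
    members = members)
  sizes <- lengths(members)
  # all nodes significant: only the root's immediate children survive
  # (root excluded, every deeper node absorbed by its ancestor)
  au <- rep(0.99, length(members))
  picked <- pickClusters(hc, mk(au), threshold = 0.95)
  expect_equal(sum(picked$n_members), 5L)
  expect_false(5L %in% picked$n_members)  # root itself never returned
  expect_length(Reduce(intersect, picked$members), 0L)
  # nothing significant -> empty frame
  expect_equal(nrow(pickClusters(hc, mk(rep(0.5, length(members))))), 0L)
  # two disjoint significant pairs are both kept
  au2 <- ifelse(sizes == 2, 0.99, 0.5)
  picked2 <- pickClusters(hc, mk(au2), threshold = 0.95)
  expect_equal(sort(picked2$n_members), c(2L, 2L))
  expect_length(Reduce(intersect, picked2$members), 0L)
})

test_that("Newick export round-trips the leaf set", {
  X <- matrix(runif(20), 5, 4,
              dimnames = list(paste0("plant", 1:5), NULL))
  tf <- withr::local_tempfile()
  exportNewick(plantDendrogram(X), tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, rownames(X))
})
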