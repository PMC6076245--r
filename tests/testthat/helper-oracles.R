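# Independent oracles used by the unit and acceptance tests. All graph
# oracles go through igraph (the package's own hierarchy code is
# hand-rolled BFS), and the statistical oracles are explicit
# enumerations, so each check compares two independent routes.

# random rooted DAG: node i > 1 draws 1-2 parents among earlier nodes
randomDagEdges <- function(n, seed, maxParents = 2L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  parent <- character(); child <- character()
  for (i in 2:n) {
    k <- sample(seq_len(min(maxParents, i - 1L)), 1L)
    p <- sample(ids[seq_len(i - 1L)], k)
    parent <- c(parent, p)
    child <- c(child, rep(ids[i], k))
  }
  data.frame(parent = parent, child = child, stringsAsFactors = FALSE)
}

.oracleGraph <- function(edges) {
  igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                directed = TRUE)
}

# node-counting depth of every vertex from the root, via igraph BFS
oracleDepths <- function(edges, root) {
  g <- .oracleGraph(edges)
  d <- igraph::distances(g, v = root, mode = "out")[1, ]
  d + 1
}

oracleAncestors <- function(edges, id) {
  g <- .oracleGraph(edges)
  names(igraph::subcomponent(g, id, mode = "in"))
}

oracleLcs <- function(edges, root, c1, c2) {
  common <- intersect(oracleAncestors(edges, c1), oracleAncestors(edges, c2))
  d <- oracleDepths(edges, root)[common]
  sort(common[d == max(d)])[1]
}

oracleWup <- function(edges, root, c1, c2) {
  if (c1 == c2) return(1)
  l <- oracleLcs(edges, root, c1, c2)
  g <- .oracleGraph(edges)
  d <- igraph::distances(g, v = l, mode = "out")[1, ]
  dl <- oracleDepths(edges, root)[[l]]
  2 * dl / (d[[c1]] + d[[c2]] + 2 * dl)
}

# exact hypergeometric upper tail by summation over the support
oracleFisherGreater <- function(a, b, c, d) {
  K <- a + c; n <- a + b; N <- a + b + c + d
  xs <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(probs[xs >= a])
}

# AUROC as the fraction of concordant positive/negative pairs
oracleAuroc <- function(scores, positives) {
  pos <- scores[names(scores) %in% positives]
  neg <- scores[!names(scores) %in% positives]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPR by walking the ranked list and summing precision at each hit
oracleAupr <- function(scores, positives) {
  ord <- order(-scores, names(scores))
  lab <- names(scores)[ord] %in% positives
  tp <- 0; s <- 0
  for (i in seq_along(lab)) {
    if (lab[i]) {
      tp <- tp + 1
      s <- s + tp / i
    }
  }
  s / sum(lab)
}

# a random weighted network for diffusion tests
randomWeightedNetwork <- function(n, seed) {
  weightEdges(buildNetwork(randomDagEdges(n, seed)))
}

# small synthetic parameter set for fast pipeline tests
smallParams <- function(seed = 1L, ...) {
  synthParams(treeDepth = 3L, branching = 2L, nThemes = 2L,
              plantsPerTheme = 4L, annotationsPerPlant = 2L,
              annotationNoise = 0, compoundsPerTheme = 2L,
              pIn = 1, pOut = 0, nBackgroundCompounds = 3L,
              backgroundPresence = 0.5, seed = seed, ...)
}
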