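#' Read hierarchical concept relations from an MRREL-style TSV
#'
#' Parses a three-column TSV of `(concept1, relation, concept2)` rows in
#' which `relation` is `RB` (concept pair related as broader) or `RN`
#' (narrower). Rows with any other relation are skipped and counted. An
#' optional header row is tolerated when the first field equals `"CUI1"`.
#'
#' Under the default orientation convention an `RB` row states that the
#' *second* concept is broader than the first, so `(A, RB, B)` becomes the
#' hierarchy edge `B -> A`; `RN` is the inverse statement. The convention
#' is reversible via `rbSecondBroader = FALSE` because terminology exports
#' differ in which side the relation describes.
#'
#' @param path path to the relations TSV (no header by default).
#' @param rbSecondBroader logical; if `TRUE` (default) an `RB` row makes
#'   the second concept the parent.
#' @return data.frame with columns `parent`, `child` (deduplicated,
#'   self-relations dropped). Attribute `skipped` holds the count of rows
#'   with unknown relation codes.
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tRB\tB", "B\tRN\tA", "A\tSY\tC"), tf)
#' readRelations(tf)   # single edge B -> A, one skip
#' @export
readRelations <- function(path, rbSecondBroader = TRUE) {
  if (!file.exists(path))
    stop("relations file not found: ", path)
  raw <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "", colClasses = "character")
  if (ncol(raw) < 3L)
    stop("relations file must have 3 tab-separated columns ",
         "(concept1, relation, concept2)")
  raw <- raw[, 1:3]
  names(raw) <- c("c1", "rel", "c2")
  if (nrow(raw) && raw$c1[1L] == "CUI1")
    raw <- raw[-1L, , drop = FALSE]
  known <- raw$rel %in% c("RB", "RN")
  nSkip <- sum(!known)
  if (nSkip)
    message("readRelations: skipped ", nSkip, " row(s) with unknown relation")
  raw <- raw[known, , drop = FALSE]
  # orient to parent (broader) -> child (narrower)
  isRB <- raw$rel == "RB"
  if (rbSecondBroader) {
    parent <- ifelse(isRB, raw$c2, raw$c1)
    child  <- ifelse(isRB, raw$c1, raw$c2)
  } else {
    parent <- ifelse(isRB, raw$c1, raw$c2)
    child  <- ifelse(isRB, raw$c2, raw$c1)
  }
  keep <- parent != child & nzchar(parent) & nzchar(child)
  edges <- unique(data.frame(parent = parent[keep], child = child[keep],
                             stringsAsFactors = FALSE))
  if (nrow(edges) == 0L)
    stop("no usable RB/RN edges in ", path)
  rownames(edges) <- NULL
  attr(edges, "skipped") <- nSkip
  edges
}

.adjacencyList <- function(from, to, nodes) {
  idx <- split(to, factor(from, levels = nodes))
  lapply(idx, function(v) sort(unique(v)))
}

# Deterministic cycle breaking: iterative DFS over children sorted by id,
# entered from roots (then any unvisited node) in lexicographic order.
# An edge into a node currently on the DFS stack is a back-edge and dropped.
.breakCycles <- function(edges) {
  nodes <- sort(unique(c(edges$parent, edges$child)))
  kids <- .adjacencyList(edges$parent, edges$child, nodes)
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 gray 2 black
  drop <- character()
  starts <- c(setdiff(nodes, unique(edges$child)), nodes)
  for (s in starts) {
    if (state[s] != 0L) next
    stack <- list(list(node = s, next_i = 1L))
    state[s] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ch <- kids[[top$node]]
      if (top$next_i > length(ch)) {
        state[top$node] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      v <- ch[top$next_i]
      stack[[length(stack)]]$next_i <- top$next_i + 1L
      key <- paste0(top$node, "\r", v)
      if (key %in% drop) next
      if (state[v] == 1L) {
        drop <- c(drop, key)           # back-edge: breaks the cycle
      } else if (state[v] == 0L) {
        state[v] <- 1L
        stack[[length(stack) + 1L]] <- list(node = v, next_i = 1L)
      }
    }
  }
  if (length(drop)) {
    message("buildNetwork: dropped ", length(drop),
            " back-edge(s) to break cycles")
    keys <- paste0(edges$parent, "\r", edges$child)
    edges <- edges[!keys %in% drop, , drop = FALSE]
  }
  edges
}

.bfsDepths <- function(root, kids, nodes) {
  depth <- setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[root] <- 1L
  frontier <- root
  while (length(frontier)) {
    nxt <- character()
    for (u in frontier) {
      for (v in kids[[u]]) {
        if (is.na(depth[v])) {
          depth[v] <- depth[u] + 1L
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  depth
}

#' Build a rooted phenotype DAG from hierarchy edges
#'
#' Cycles are broken by dropping the back-edge first encountered in a
#' deterministic depth-first traversal (children visited in lexicographic
#' order); each drop is reported. If several concepts remain parentless a
#' virtual root is inserted above all of them so that depth and lowest
#' common subsumers are always defined.
#'
#' @param edges data.frame with columns `parent`, `child`, e.g. from
#'   [readRelations()].
#' @param virtualRootId identifier used for the synthesised root when one
#'   is needed; must not collide with an existing concept.
#' @return a [PhenotypeNetwork-class] (unweighted; see [weightEdges()]).
#' @examples
#' net <- buildNetwork(data.frame(parent = c("R", "A"), child = c("A", "B")))
#' rootConcept(net)
#' @export
buildNetwork <- function(edges, virtualRootId = "VROOT") {
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges <- unique(edges[edges$parent != edges$child, c("parent", "child")])
  if (nrow(edges) == 0L) stop("empty hierarchy edge list")
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  edges <- .breakCycles(edges)
  nodes <- sort(unique(c(edges$parent, edges$child)))
  roots <- setdiff(nodes, unique(edges$child))
  virtual <- FALSE
  if (length(roots) == 0L)
    stop("hierarchy has no parentless concept after cycle breaking")
  if (length(roots) > 1L) {
    if (virtualRootId %in% nodes)
      stop("virtual root id collides with an existing concept: ",
           virtualRootId)
    edges <- rbind(edges,
                   data.frame(parent = virtualRootId, child = roots,
                              stringsAsFactors = FALSE))
    nodes <- c(virtualRootId, nodes)
    root <- virtualRootId
    virtual <- TRUE
  } else {
    root <- roots
  }
  nodes <- sort(nodes)
  kids <- .adjacencyList(edges$parent, edges$child, nodes)
  pars <- .adjacencyList(edges$child, edges$parent, nodes)
  depth <- .bfsDepths(root, kids, nodes)
  # acyclic + every non-root has a parent => all nodes reachable from root
  stopifnot(!anyNA(depth))
  edges$weight <- NA_real_
  rownames(edges) <- NULL
  new("PhenotypeNetwork", concepts = nodes, edges = edges, root = root,
      virtualRoot = virtual, depths = depth,
      childIndex = kids, parentIndex = pars)
}

.checkConcept <- function(network, id) {
  miss <- setdiff(id, network@concepts)
  if (length(miss))
    stop("unknown concept(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Depth of a concept in the hierarchy
#'
#' Depth counts the nodes on the shortest hierarchy path from the root to
#' the concept, inclusive: the root has depth 1. With multiple parents the
#' shortest path wins.
#'
#' @param network a [PhenotypeNetwork-class].
#' @param id concept identifier(s).
#' @return integer depth(s), named when `id` has length > 1.
#' @export
conceptDepth <- function(network, id) {
  .checkConcept(network, id)
  d <- network@depths[id]
  if (length(id) == 1L) unname(d) else d
}

# all ancestors of a concept, including itself (upward BFS)
.ancestors <- function(network, id) {
  seen <- id
  frontier <- id
  while (length(frontier)) {
    up <- unique(unlist(network@parentIndex[frontier], use.names = FALSE))
    up <- setdiff(up, seen)
    seen <- c(seen, up)
    frontier <- up
  }
  seen
}

# edge count of the shortest descending hierarchy path anc -> id
.downPath <- function(network, anc, id) {
  if (anc == id) return(0L)
  dist <- 0L
  frontier <- anc
  seen <- anc
  repeat {
    dist <- dist + 1L
    frontier <- setdiff(
      unique(unlist(network@childIndex[frontier], use.names = FALSE)), seen)
    if (id %in% frontier) return(dist)
    if (length(frontier) == 0L)
      stop("no descending path from ", anc, " to ", id)
    seen <- c(seen, frontier)
  }
}

#' Lowest common subsumer of two concepts
#'
#' The common ancestor of maximal depth, where a concept counts among its
#' own ancestors. Ties between equally deep common ancestors (possible in
#' a DAG) are broken by the lexicographically smallest identifier.
#'
#' @inheritParams conceptDepth
#' @param c1,c2 concept identifiers.
#' @return the identifier of the lowest common subsumer.
#' @export
lowestCommonSubsumer <- function(network, c1, c2) {
  .checkConcept(network, c(c1, c2))
  common <- intersect(.ancestors(network, c1), .ancestors(network, c2))
  d <- network@depths[common]
  cand <- sort(common[d == max(d)])
  cand[1L]
}

#' Wu-Palmer semantic similarity between two concepts
#'
#' \deqn{sim(c_1, c_2) = \frac{2\,depth(lcs)}{path(c_1, lcs) +
#'   path(c_2, lcs) + 2\,depth(lcs)}}
#' where `lcs` is the lowest common subsumer, `depth` counts nodes from
#' the root (root depth 1) and `path(x, lcs)` counts edges on the shortest
#' descending path from the subsumer to `x`. The score lies in (0, 1],
#' is symmetric, and equals 1 exactly when the concepts coincide.
#'
#' @inheritParams lowestCommonSubsumer
#' @return numeric similarity in (0, 1].
#' @examples
#' net <- buildNetwork(data.frame(parent = c("R", "A"), child = c("A", "B")))
#' wupSimilarity(net, "A", "B")   # 0.8
#' @export
wupSimilarity <- function(network, c1, c2) {
  .checkConcept(network, c(c1, c2))
  if (c1 == c2) return(1)
  l <- lowestCommonSubsumer(network, c1, c2)
  dl <- as.numeric(network@depths[l])
  p1 <- .downPath(network, l, c1)
  p2 <- .downPath(network, l, c2)
  2 * dl / (p1 + p2 + 2 * dl)
}

#' Assign Wu-Palmer similarity weights to all hierarchy edges
#'
#' Every hierarchy edge `(u, v)` gets the weight `wupSimilarity(u, v)`.
#' Propagation over the weighted network treats edges as undirected, so
#' the weight applies symmetrically. Deeper edges carry larger weights:
#' a parent at depth `d` linked to its child scores `2d / (1 + 2d)`
#' whenever the parent is the pair's subsumer, so similarity grows with
#' specificity.
#'
#' @param network a [PhenotypeNetwork-class] from [buildNetwork()].
#' @return the network with the `weight` column filled.
#' @export
weightEdges <- function(network) {
  e <- network@edges
  e$weight <- vapply(seq_len(nrow(e)), function(i)
    wupSimilarity(network, e$parent[i], e$child[i]), numeric(1))
  network@edges <- e
  validObject(network)
  network
}

#' Write / read a weighted network as an edge-list TSV
#'
#' Serialization for inspection and reload: tab-separated columns
#' `parent`, `child`, `weight` with a header row.
#'
#' @param network a weighted [PhenotypeNetwork-class].
#' @param path output file path.
#' @return `writeNetwork` returns `path` invisibly; `readNetwork` returns
#'   a rebuilt [PhenotypeNetwork-class] with the stored weights.
#' @export
writeNetwork <- function(network, path) {
  write.table(network@edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  e <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c("character", "character", "numeric"))
  # weights are a pure function of the topology; recomputing them on
  # reload avoids the serialization's decimal truncation, so chained
  # stage runs stay byte-identical with a single in-memory run
  weightEdges(buildNetwork(e[, c("parent", "child")]))
}
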