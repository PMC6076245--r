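#' Column-normalized transition matrix of a weighted network
#'
#' The propagation graph treats hierarchy edges as undirected: the
#' symmetric weighted adjacency matrix is normalized column-wise so that
#' every column sums to one. Concepts with no incident edge receive a
#' unit self-loop so the matrix stays column-stochastic.
#'
#' @param network a weighted [PhenotypeNetwork-class].
#' @return a sparse column-stochastic `dgCMatrix` (concepts x concepts,
#'   dimnames set).
#' @export
transitionMatrix <- function(network) {
  e <- network@edges
  if (anyNA(e$weight))
    stop("network is unweighted; run weightEdges() first")
  nodes <- network@concepts
  i <- match(e$child, nodes)
  j <- match(e$parent, nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = c(e$weight, e$weight),
                            dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  cs <- Matrix::colSums(A)
  isolated <- which(cs == 0)
  if (length(isolated)) {
    A <- A + Matrix::sparseMatrix(i = isolated, j = isolated,
                                  x = rep(1, length(isolated)),
                                  dims = dim(A), dimnames = dimnames(A))
    cs[isolated] <- 1
  }
  W <- A %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(W) <- list(nodes, nodes)
  methods::as(W, "CsparseMatrix")
}

#' Seed probability vector of a plant
#'
#' Uniform initial probability over the plant's efficacy concepts that
#' map into the network; unmapped annotations are skipped with a message.
#'
#' @param efficacy character vector of annotated concept identifiers.
#' @param network a [PhenotypeNetwork-class].
#' @param id optional plant identifier used in messages.
#' @return named numeric vector over all network concepts, summing to 1.
#' @export
makeSeed <- function(efficacy, network, id = NULL) {
  efficacy <- unique(efficacy)
  mapped <- intersect(efficacy, network@concepts)
  nSkip <- length(efficacy) - length(mapped)
  if (nSkip)
    message("makeSeed: ", if (!is.null(id)) paste0(id, ": "), nSkip,
            " annotation(s) not in the network, skipped")
  if (length(mapped) == 0L)
    stop("no efficacy concept of ",
         if (is.null(id)) "this plant" else id, " maps into the network")
  p0 <- setNames(numeric(length(network@concepts)), network@concepts)
  p0[mapped] <- 1 / length(mapped)
  p0
}

.checkStochastic <- function(W) {
  cs <- Matrix::colSums(W)
  if (any(abs(cs - 1) > 1e-8) || min(W) < 0)
    stop("transition matrix is not column-stochastic")
  invisible(TRUE)
}

#' Random walk with restart to steady state
#'
#' Iterates \eqn{p_{t+1} = (1 - r)\, W p_t + r p_0} from \eqn{p_0} until
#' the L1 change drops below `tol`, where `W` is the column-stochastic
#' transition matrix with `W[i, j]` the probability of stepping from
#' concept `j` to concept `i` (equivalently, the transpose of the
#' row-oriented transition matrix). With this convention the iterate
#' remains a probability vector -- mass is conserved exactly -- and the
#' restart term guarantees geometric convergence.
#'
#' @param W column-stochastic transition matrix (see [transitionMatrix()]).
#' @param p0 seed probability vector (sums to 1), named like `W`'s rows.
#' @param r restart probability in (0, 1); default 0.7.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param maxIter iteration cap (default 10000); exceeding it is an error.
#' @return named steady-state probability vector.
#' @seealso [rwrClosedForm()] for the direct linear solve.
#' @export
rwr <- function(W, p0, r = 0.7, tol = 1e-8, maxIter = 10000L) {
  stopifnot(r > 0, r < 1, abs(sum(p0) - 1) < 1e-9)
  .checkStochastic(W)
  p <- p0
  for (it in seq_len(maxIter)) {
    pNew <- as.numeric((1 - r) * (W %*% p)) + r * p0
    delta <- sum(abs(pNew - p))
    p <- pNew
    if (delta < tol) {
      names(p) <- names(p0)
      return(p)
    }
  }
  stop("rwr did not converge within ", maxIter, " iterations")
}

#' Closed-form steady state of the random walk with restart
#'
#' Solves the fixed-point system \eqn{p = r (I - (1-r) W)^{-1} p_0}
#' directly (same operator convention as [rwr()]: `W` column-stochastic,
#' acting on the left). Serves as the exact reference for the iterative [rwr()]
#' and as the fast path when many seeds share one network: `p0` may be a
#' matrix with one seed per column, factorized once.
#'
#' @inheritParams rwr
#' @param p0 seed vector, or a matrix of seed columns.
#' @return steady-state vector (or matrix, one column per seed).
#' @export
rwrClosedForm <- function(W, p0, r = 0.7) {
  stopifnot(r > 0, r < 1)
  .checkStochastic(W)
  A <- Matrix::Diagonal(nrow(W)) - (1 - r) * W
  sol <- Matrix::solve(A, r * (if (is.matrix(p0)) Matrix::Matrix(p0) else p0))
  if (is.matrix(p0)) {
    out <- as.matrix(sol)
    dimnames(out) <- dimnames(p0)
    out
  } else {
    setNames(as.numeric(sol), names(p0))
  }
}

#' Project a steady state onto the phenotype universe
#'
#' Restricts a steady-state vector over all network concepts to the
#' ordered phenotype universe, preserving values (no renormalization, so
#' scores stay comparable across plants).
#'
#' @param steady named steady-state vector from [rwr()] /
#'   [rwrClosedForm()].
#' @param universe ordered character vector of universe concepts; every
#'   entry must be a network concept present in `steady`.
#' @return numeric vector of length `length(universe)`, named by concept.
#' @export
plantVector <- function(steady, universe) {
  miss <- setdiff(universe, names(steady))
  if (length(miss))
    stop("universe concept(s) absent from the network: ",
         paste(head(miss, 5), collapse = ", "))
  steady[universe]
}

#' RWR phenotype vectors for a set of plants
#'
#' Builds the seed of every plant, diffuses it over the weighted network
#' and projects onto the universe, producing the plants x phenotypes
#' matrix that downstream clustering consumes. Plants whose annotations
#' do not map into the network at all are excluded with a message.
#'
#' For networks up to `denseLimit` concepts the steady states are
#' obtained by one factorized linear solve over all plants; larger
#' networks fall back to the per-plant sparse iteration. Both routes
#' agree within the iteration tolerance.
#'
#' @param network a weighted [PhenotypeNetwork-class].
#' @param profiles named list: plant id -> character vector of efficacy
#'   concepts.
#' @param universe ordered phenotype universe.
#' @inheritParams rwr
#' @param denseLimit network size up to which the direct solve is used.
#' @return numeric matrix, plants (rows) x universe phenotypes (columns).
#' @export
phenotypeVectors <- function(network, profiles, universe, r = 0.7,
                             tol = 1e-8, denseLimit = 2000L) {
  W <- transitionMatrix(network)
  seeds <- list()
  for (id in names(profiles)) {
    p0 <- tryCatch(makeSeed(profiles[[id]], network, id = id),
                   error = function(e) NULL)
    if (is.null(p0)) {
      message("phenotypeVectors: plant ", id,
              " has no mappable annotation, excluded")
      next
    }
    seeds[[id]] <- p0
  }
  if (length(seeds) == 0L) stop("no plant could be mapped onto the network")
  if (length(network@concepts) <= denseLimit) {
    P0 <- do.call(cbind, seeds)
    steady <- rwrClosedForm(W, P0, r = r)
  } else {
    steady <- vapply(seeds, function(p0) rwr(W, p0, r = r, tol = tol),
                     numeric(nrow(W)))
    rownames(steady) <- rownames(W)
  }
  X <- t(steady[universe, , drop = FALSE])
  colnames(X) <- universe
  X
}

#' Binary no-hierarchy phenotype vectors (ablation)
#'
#' The hierarchy-free counterpart of [phenotypeVectors()]: each plant's
#' vector is the 0/1 indicator of its directly annotated universe
#' phenotypes, with no diffusion. Used to measure what the hierarchical
#' propagation adds.
#'
#' @param profiles named list: plant id -> annotated concepts.
#' @param universe ordered phenotype universe.
#' @return binary matrix, plants x universe phenotypes. Plants with no
#'   annotation inside the universe are excluded with a message.
#' @export
ablationVectors <- function(profiles, universe) {
  keep <- vapply(profiles, function(a) any(a %in% universe), logical(1))
  if (any(!keep))
    message("ablationVectors: excluded ", sum(!keep),
            " plant(s) with no universe annotation")
  profiles <- profiles[keep]
  if (length(profiles) == 0L) stop("no plant annotates the universe")
  X <- matrix(0, nrow = length(profiles), ncol = length(universe),
              dimnames = list(names(profiles), universe))
  for (id in names(profiles))
    X[id, intersect(profiles[[id]], universe)] <- 1
  X
}
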